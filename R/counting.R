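# Region labelling, concave corner-point detection, the per-region count
# formula, the linear-adhesion correction and the whole-image count.

round_half_up <- function(x) floor(x + 0.5)

#' Label grain regions
#'
#' 8-connected foreground components of a binary mask, with the geometry
#' the counting stage needs: area, bounding box, centroid, enclosed holes,
#' skeleton and short axis. Components below \code{cfg$min_blob_area} are
#' dropped.
#'
#' @param mask Integer 0/1 matrix.
#' @param cfg A [grain_config()].
#' @return A tibble with one row per region: \code{id}, \code{area},
#'   \code{centroid_r}, \code{centroid_c}, \code{holes},
#'   \code{short_axis}, \code{skeleton_length}, and list columns
#'   \code{bbox} (top, left, height, width), \code{mask} (the region's
#'   local 0/1 crop) and \code{skeleton}.
#' @export
label_regions <- function(mask, cfg = grain_config()) {
  mask <- drop_small_components(mask, cfg$min_blob_area)
  lab <- label_components(mask, 8L)
  build_regions(lab, dim(mask))
}

# linear pixel indices per label, plus (row, col) decoding
label_pixels <- function(lab) {
  fg <- which(lab > 0L)
  split(fg, lab[fg])
}

decode_rc <- function(idx, nr) {
  cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
}

# build the region table from a label matrix (labels 1..n, 0 = background)
build_regions <- function(lab, img_dim) {
  nlab <- max(lab)
  if (nlab == 0) {
    return(tibble::tibble(id = integer(0), area = numeric(0),
                          centroid_r = numeric(0), centroid_c = numeric(0),
                          holes = integer(0), short_axis = numeric(0),
                          skeleton_length = numeric(0), bbox = list(),
                          mask = list(), skeleton = list()))
  }
  plist <- label_pixels(lab)
  rows <- vector("list", nlab)
  for (i in seq_len(nlab)) {
    rc <- decode_rc(plist[[as.character(i)]], nrow(lab))
    rr <- range(rc[, 1]); cr <- range(rc[, 2])
    bb <- c(rr[1], cr[1], rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
    crop <- matrix(0L, bb[3], bb[4])
    crop[cbind(rc[, 1] - bb[1] + 1L, rc[, 2] - bb[2] + 1L)] <- 1L
    px <- which(crop == 1L, arr.ind = TRUE)
    sk <- skeletonize_crop(crop)
    sa <- estimate_short_axis(pad_mask(crop, 1L), shift_skel(sk, 1L, 1L))
    rows[[i]] <- tibble::tibble(
      id = i,
      area = nrow(px),
      centroid_r = mean(px[, 1]) + bb[1] - 1,
      centroid_c = mean(px[, 2]) + bb[2] - 1,
      holes = count_holes(crop),
      short_axis = sa$X,
      skeleton_length = sk$total_length,
      bbox = list(bb),
      mask = list(crop),
      skeleton = list(sk)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "img_dim") <- img_dim
  out
}

pad_mask <- function(m, p) {
  out <- matrix(0L, nrow(m) + 2 * p, ncol(m) + 2 * p)
  out[(p + 1):(p + nrow(m)), (p + 1):(p + ncol(m))] <- m
  out
}

shift_skel <- function(sk, dr, dc) {
  sk$pixels[, 1] <- sk$pixels[, 1] + dr
  sk$pixels[, 2] <- sk$pixels[, 2] + dc
  sk
}

#' Count enclosed holes of a region
#'
#' A hole is a 4-connected background component fully surrounded by the
#' region's pixels (for example the gap inside a closed ring of touching
#' grains). Counted by labelling the background of the region's padded
#' crop: every background component except the one touching the outside
#' is a hole.
#'
#' @param region_mask Integer 0/1 matrix holding one region (a local crop
#'   is fine), or a row of [label_regions()] output.
#' @return Integer hole count.
#' @export
count_holes <- function(region_mask) {
  if (is.data.frame(region_mask)) region_mask <- region_mask$mask[[1]]
  padded <- pad_mask(region_mask, 1L)
  bg <- 1L - padded
  labs <- label_components(bg, 4L)
  max(labs) - 1L
}

#' Detect concave corner points on a region boundary
#'
#' Every boundary pixel of the region is scored by the foreground fraction
#' of the window (side \code{cfg$corner_window}) centred on it; where two
#' convex grains meet, the boundary bends inwards and the window fills
#' with grain pixels from both, pushing the fraction above what any convex
#' boundary can reach (about 0.5). Pixels whose fraction strictly exceeds
#' \code{cfg$corner_fraction} are candidates; non-maximum suppression
#' keeps candidates that are fraction maxima within a Chebyshev radius of
#' \code{cfg$corner_window}, ties resolved in scan order (top-to-bottom,
#' left-to-right). Pixels beyond the photo border count as background (the
#' paper sheet continues past the frame), so fractions are always over the
#' full window area.
#'
#' @param region One row of a [label_regions()] table (or the whole table,
#'   in which case its first row is used).
#' @param mask Optional full-size 0/1 matrix on which window fractions are
#'   computed; when omitted, fractions are computed on the region's own
#'   geometry (the right choice after adhesion splitting).
#' @param cfg A [grain_config()].
#' @return Tibble of corners: \code{row}, \code{col} (image coordinates)
#'   and \code{score}. Convex regions legitimately return zero rows.
#' @export
detect_corners <- function(region, mask = NULL, cfg = grain_config()) {
  if (is.data.frame(region) && nrow(region) > 1) region <- region[1, ]
  bb <- region$bbox[[1]]
  crop <- region$mask[[1]]
  img_dim <- attr(region, "img_dim")
  if (is.null(img_dim)) img_dim <- if (!is.null(mask)) dim(mask) else bb[3:4] + bb[1:2] - 1
  rad <- cfg$corner_window %/% 2
  # expand the crop by up to `rad`, clipped at the photo border so window
  # clipping at the matrix edge coincides with clipping at the photo edge
  top <- max(1L, bb[1] - rad); left <- max(1L, bb[2] - rad)
  bot <- min(img_dim[1], bb[1] + bb[3] - 1L + rad)
  right <- min(img_dim[2], bb[2] + bb[4] - 1L + rad)
  if (!is.null(mask)) {
    fmat <- mask[top:bot, left:right, drop = FALSE]
  } else {
    fmat <- matrix(0L, bot - top + 1L, right - left + 1L)
    fmat[(bb[1] - top + 1):(bb[1] - top + bb[3]),
         (bb[2] - left + 1):(bb[2] - left + bb[4])] <- crop
  }
  frac <- window_fraction_cpp(fmat, cfg$corner_window)
  bpx <- boundary_pixels(crop)           # local crop coordinates
  if (nrow(bpx) == 0) return(corner_tibble())
  fr <- bpx[, 1] + bb[1] - top           # rows in fmat frame
  fc <- bpx[, 2] + bb[2] - left
  scores <- frac[cbind(fr, fc)]
  cand <- scores > cfg$corner_fraction
  if (!any(cand)) return(corner_tibble())
  crow <- bpx[cand, 1] + bb[1] - 1L
  ccol <- bpx[cand, 2] + bb[2] - 1L
  cscore <- scores[cand]
  keep <- nms_chebyshev(crow, ccol, cscore, cfg$corner_window)
  tibble::tibble(row = crow[keep], col = ccol[keep], score = cscore[keep])
}

corner_tibble <- function() {
  tibble::tibble(row = integer(0), col = integer(0), score = numeric(0))
}

# region pixels with a 4-neighbour outside the region (or outside the image)
boundary_pixels <- function(crop) {
  p <- pad_mask(crop, 1L)
  inner <- p[2:(nrow(p) - 1), 2:(ncol(p) - 1), drop = FALSE]
  nb <- p[1:(nrow(p) - 2), 2:(ncol(p) - 1), drop = FALSE] +
        p[3:nrow(p),       2:(ncol(p) - 1), drop = FALSE] +
        p[2:(nrow(p) - 1), 1:(ncol(p) - 2), drop = FALSE] +
        p[2:(nrow(p) - 1), 3:ncol(p),       drop = FALSE]
  which(inner == 1L & nb < 4L, arr.ind = TRUE)
}

# greedy non-maximum suppression; ties by scan order (row, then col)
nms_chebyshev <- function(rows, cols, scores, radius) {
  ord <- order(-scores, rows, cols)
  keep <- logical(length(scores))
  for (i in ord) {
    if (any(keep & pmax(abs(rows - rows[i]), abs(cols - cols[i])) <= radius)) next
    keep[i] <- TRUE
  }
  which(keep)
}

#' Per-region grain count from corners and holes
#'
#' The count of a connected region with \code{n_corners} detected concave
#' corner points and \code{holes} enclosed background holes is
#' \deqn{n_{corners} / 2 - holes + 1.}
#' Each junction between two adhered grains exposes two concave corners,
#' so a chain of k grains has 2(k-1) corners and counts k; a closed ring
#' gains one spurious unit from its cycle, which the hole term removes.
#' Fractional output (an odd corner count) signals an occluded corner.
#'
#' @param n_corners Number of detected corner points (>= 0).
#' @param holes Number of enclosed holes (>= 0).
#' @return Fractional grain count.
#' @export
region_count_formula <- function(n_corners, holes) {
  stopifnot(all(n_corners >= 0), all(holes >= 0))
  n_corners / 2 - holes + 1
}

#' Is a region a near-collinear ("linear") adhesion?
#'
#' Two grains overlapping almost end-to-end hide one of the two junction
#' corners, so the corner formula lands on a half value. Such regions are
#' recognised by their skeleton: it is much longer than the image average
#' (factor \code{cfg$length_factor}) and almost straight — the clockwise
#' included angle at the midpoint of the longest skeleton path, measured
#' between least-squares line fits to the path's two halves, falls in
#' \code{cfg$angle_band} (180 degrees = perfectly straight).
#'
#' @param region One row of a [label_regions()] table.
#' @param mean_skeleton_length Mean skeleton length over all regions of
#'   the image (px).
#' @param cfg A [grain_config()].
#' @return Logical.
#' @export
is_linear_adhesion <- function(region, mean_skeleton_length,
                               cfg = grain_config()) {
  if (is.data.frame(region) && nrow(region) > 1) region <- region[1, ]
  sk <- region$skeleton[[1]]
  if (!(sk$total_length > cfg$length_factor * mean_skeleton_length)) {
    return(FALSE)
  }
  ang <- skeleton_included_angle(sk)
  if (is.na(ang)) return(FALSE)
  ang >= cfg$angle_band[1] && ang <= cfg$angle_band[2]
}

# clockwise included angle (degrees) at the midpoint of the longest
# skeleton path; NA when the path has fewer than 3 pixels
skeleton_included_angle <- function(sk) {
  path <- sk$longest_path
  n <- nrow(path)
  if (n < 3) return(NA_real_)
  steps <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(steps))
  mid <- which.min(abs(arc - arc[n] / 2))
  if (mid < 2 || mid > n - 1) mid <- max(2, min(n - 1, mid))
  d1 <- fit_direction(path[1:mid, , drop = FALSE],
                      path[mid, ] - path[1, ])
  d2 <- fit_direction(path[mid:n, , drop = FALSE],
                      path[n, ] - path[mid, ])
  turn <- atan2(d1[1] * d2[2] - d1[2] * d2[1], sum(d1 * d2)) * 180 / pi
  ang <- 180 + turn
  ang %% 360
}

# least-squares (principal axis) direction of a point run, oriented along
# the chord
fit_direction <- function(pts, chord) {
  if (nrow(pts) < 2 || all(chord == 0)) return(c(1, 0))
  v <- prcomp(pts, center = TRUE)$rotation[, 1]
  if (sum(v * chord) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Average-area fallback count
#'
#' For linear adhesions the corner formula undercounts, so the region's
#' count is its area divided by the mean single-grain area, rounded half
#' up and floored at 1.
#'
#' @param region_area Region area in px^2.
#' @param mean_single_area Mean area of single grains in the image (px^2,
#'   > 0).
#' @return Integer count >= 1.
#' @export
average_area_count <- function(region_area, mean_single_area) {
  stopifnot(mean_single_area > 0)
  max(1L, as.integer(round_half_up(region_area / mean_single_area)))
}

#' Count all grains in a binarized image
#'
#' The full counting pipeline:
#' \enumerate{
#'   \item Split adhesions with short-axis-scaled erosion ([separate()]).
#'   \item Where a region fell into several fragments, partition the
#'     original (pre-erosion) region geometry among the fragments by
#'     seeded region growing, so every counting unit keeps its true grain
#'     outline — erosion only decides the split lines, it never supplies
#'     the geometry corners and holes are measured on.
#'   \item Score every unit: concave corners, enclosed holes, skeleton.
#'   \item Units with no corners and no holes that fail the
#'     linear-adhesion test count as one grain. Linear adhesions are
#'     counted by the average-area fallback. Everything else gets the
#'     corner formula \code{corners/2 - holes + 1}, rounded half up and
#'     floored at 1.
#' }
#' The mean single-grain area is taken from units whose raw corner-formula
#' value rounds to 1; when fewer than three such units exist, the median
#' unit area divided by the median raw value stands in (with a warning).
#'
#' @param mask Binarized 0/1 matrix (from [binarize()]).
#' @param cfg A [grain_config()].
#' @return A \code{grain_count} object: list with \code{total}, a
#'   \code{regions} tibble (one row per counting unit: centroid, area,
#'   corners, holes, raw value, corrected count, method), the
#'   \code{mean_single_area}, an \code{annotations} tibble and the
#'   \code{config} used.
#' @export
count_image <- function(mask, cfg = grain_config()) {
  mask <- drop_small_components(mask, cfg$min_blob_area)
  if (!any(mask == 1L)) {
    warning("empty mask: nothing to count")
    return(new_grain_count(tibble::tibble(), 0L, NA_real_, cfg, dim(mask)))
  }
  lab0 <- label_components(mask, 8L)
  sep <- separate(mask, cfg)
  units <- partition_units(mask, lab0, sep)
  regions <- build_regions(units, dim(mask))
  fgi <- which(units > 0L)
  parent <- as.integer(tapply(lab0[fgi], units[fgi], function(v) v[1]))
  ncorn <- integer(nrow(regions))
  corners <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    corners[[i]] <- detect_corners(regions[i, ], mask = NULL, cfg = cfg)
    ncorn[i] <- nrow(corners[[i]])
  }
  raw <- region_count_formula(ncorn, regions$holes)
  mean_skel <- mean(regions$skeleton_length)
  linear <- vapply(seq_len(nrow(regions)), function(i)
    is_linear_adhesion(regions[i, ], mean_skel, cfg), logical(1))
  # the single-grain pool excludes linear adhesions: their corner formula
  # also lands on 1 (or 1.5), but the length rule has flagged them as
  # multi-grain, and including them would inflate the mean single area
  singles <- round_half_up(raw) == 1 & !linear
  if (sum(singles) >= 3) {
    mean_single_area <- mean(regions$area[singles])
  } else {
    warning("fewer than 3 single grains: mean single area from median area / median raw count")
    mean_single_area <- median(regions$area) / max(median(raw), 1)
  }
  method <- character(nrow(regions))
  corrected <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    if (ncorn[i] == 0 && regions$holes[i] == 0 && !linear[i]) {
      method[i] <- "single"; corrected[i] <- 1L
    } else if (linear[i]) {
      method[i] <- "average_area"
      corrected[i] <- average_area_count(regions$area[i], mean_single_area)
    } else {
      method[i] <- "corner_formula"
      corrected[i] <- max(1L, as.integer(round_half_up(raw[i])))
    }
  }
  out <- tibble::tibble(
    region_id = regions$id,
    parent_region = parent,
    centroid_r = regions$centroid_r,
    centroid_c = regions$centroid_c,
    area = regions$area,
    corners = ncorn,
    holes = regions$holes,
    short_axis = regions$short_axis,
    skeleton_length = regions$skeleton_length,
    raw_value = raw,
    corrected = corrected,
    method = method
  )
  new_grain_count(out, sum(corrected), mean_single_area, cfg, dim(mask))
}

# assign each original-region pixel to its eroded fragment (seeded region
# growing on constant intensity = geodesic Voronoi); regions whose erosion
# did not split pass through whole
partition_units <- function(mask, lab0, sep) {
  frag <- label_components(sep, 8L)
  nlab <- max(lab0)
  units <- matrix(0L, nrow(mask), ncol(mask))
  plist <- label_pixels(lab0)
  next_id <- 0L
  for (i in seq_len(nlab)) {
    pix <- plist[[as.character(i)]]
    fl <- unique(frag[pix])
    fl <- fl[fl > 0]
    if (length(fl) <= 1) {
      next_id <- next_id + 1L
      units[pix] <- next_id
      next
    }
    rc <- decode_rc(pix, nrow(mask))
    rr <- range(rc[, 1]); cr <- range(rc[, 2])
    bb <- c(rr[1], cr[1], rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
    rows <- bb[1]:(bb[1] + bb[3] - 1); cols <- bb[2]:(bb[2] + bb[4] - 1)
    lrc <- cbind(rc[, 1] - bb[1] + 1L, rc[, 2] - bb[2] + 1L)
    mcrop <- matrix(0L, bb[3], bb[4])
    mcrop[lrc] <- 1L
    scrop <- matrix(0L, bb[3], bb[4])
    fvals <- frag[pix]
    hit <- fvals > 0
    scrop[lrc[hit, , drop = FALSE]] <- match(fvals[hit], fl)
    part <- EBImage::propagate(EBImage::Image(matrix(0, bb[3], bb[4])),
                               seeds = scrop, mask = mcrop)
    part <- as.integer(round(part))
    dim(part) <- c(bb[3], bb[4])
    sub <- units[rows, cols]
    sub[part > 0] <- next_id + part[part > 0]
    units[rows, cols] <- sub
    next_id <- next_id + length(fl)
  }
  units
}

new_grain_count <- function(regions, total, mean_single_area, cfg, img_dim) {
  ann <- if (nrow(regions) > 0) {
    tibble::tibble(row = regions$centroid_r, col = regions$centroid_c,
                   count = regions$corrected,
                   labeled = regions$corrected >= 2)
  } else {
    tibble::tibble(row = numeric(0), col = numeric(0),
                   count = integer(0), labeled = logical(0))
  }
  structure(list(total = as.integer(total), regions = regions,
                 mean_single_area = mean_single_area,
                 annotations = ann, config = cfg, img_dim = img_dim),
            class = "grain_count")
}

#' @export
print.grain_count <- function(x, ...) {
  cat(sprintf("<grain_count> total = %d grains over %d region(s)\n",
              x$total, nrow(x$regions)))
  if (nrow(x$regions) > 0) {
    tab <- table(x$regions$method)
    cat("  methods:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count grains in a photograph
#'
#' Convenience wrapper running the full pipeline on an image file or
#' array: load, downscale to \code{cfg$target_long_side}, binarize, count.
#'
#' @param image Path to a JPEG/PNG file, or an image array.
#' @param cfg A [grain_config()].
#' @return A \code{grain_count} object; the processed image is attached as
#'   attribute \code{"image"} for annotation.
#' @export
count_grains <- function(image, cfg = grain_config()) {
  img <- if (is.character(image)) load_image(image) else image
  img <- resize_long_side(img, cfg$target_long_side)
  mask <- binarize(img, cfg)
  res <- count_image(mask, cfg)
  attr(res, "image") <- img
  res
}
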