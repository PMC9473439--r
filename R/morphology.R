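# Skeletons, short-axis estimation and short-axis-scaled erosion.
#
# Masks are integer 0/1 matrices, row 1 = top of the image. Coordinates are
# (row, col), 1-based.

#' Extract the medial skeleton of every region in a mask
#'
#' Each 8-connected foreground region is thinned to a unit-width,
#' topology-preserving skeleton (components and holes survive thinning;
#' holes appear as skeleton cycles). For every region the skeleton's
#' pixels, endpoints, branch points, total length (axial step = 1 px,
#' diagonal = sqrt(2)) and the longest geodesic path are returned.
#'
#' @param mask Integer 0/1 matrix.
#' @return A list with one \code{grain_skeleton} per region, ordered by
#'   label scan order (columns left to right, rows top to bottom). An empty
#'   mask gives an empty list.
#' @export
skeletonize <- function(mask) {
  if (!any(mask == 1L)) return(list())
  lab <- label_components(mask, 8L)
  plist <- label_pixels(lab)
  lapply(seq_len(max(lab)), function(i) {
    rc <- decode_rc(plist[[as.character(i)]], nrow(mask))
    rr <- range(rc[, 1]); cr <- range(rc[, 2])
    bb <- c(rr[1], cr[1], rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
    crop <- matrix(0L, bb[3], bb[4])
    crop[cbind(rc[, 1] - bb[1] + 1L, rc[, 2] - bb[2] + 1L)] <- 1L
    sk <- skeletonize_crop(crop)
    sk$pixels[, 1] <- sk$pixels[, 1] + bb[1] - 1L
    sk$pixels[, 2] <- sk$pixels[, 2] + bb[2] - 1L
    if (nrow(sk$endpoints) > 0) {
      sk$endpoints <- sk$endpoints + rep(bb[1:2] - 1L, each = nrow(sk$endpoints))
    }
    if (nrow(sk$branch_points) > 0) {
      sk$branch_points <- sk$branch_points +
        rep(bb[1:2] - 1L, each = nrow(sk$branch_points))
    }
    sk$longest_path <- sk$longest_path + rep(bb[1:2] - 1L, each = nrow(sk$longest_path))
    sk
  })
}

# Euclidean distance to the nearest background pixel, with the matrix
# border counting as background (a grain cut by the photo edge is eroded
# from that side too)
distmap_bg <- function(mask) {
  p <- pad_mask(mask, 1L)
  d <- EBImage::distmap(p)
  d[2:(nrow(p) - 1), 2:(ncol(p) - 1), drop = FALSE]
}

# bounding box of a logical matrix: (top row, left col, height, width)
bbox_of <- function(lg) {
  rs <- range(which(rowSums(lg) > 0))
  cs <- range(which(colSums(lg) > 0))
  c(rs[1], cs[1], rs[2] - rs[1] + 1L, cs[2] - cs[1] + 1L)
}

# skeletonize a single-region crop and compute path statistics
skeletonize_crop <- function(crop) {
  thin <- thin_mask(crop)
  px <- which(thin == 1L, arr.ind = TRUE)
  dimnames(px) <- NULL
  n <- nrow(px)
  if (n == 1) {
    sk <- list(pixels = px, endpoints = px,
               branch_points = px[0, , drop = FALSE],
               total_length = 0, longest_path = px, n_pixels = 1L)
    class(sk) <- "grain_skeleton"
    return(sk)
  }
  # index skeleton pixels for adjacency lookup
  idx <- matrix(0L, nrow(crop), ncol(crop))
  idx[px] <- seq_len(n)
  # candidate edges: each 8-neighbour pair once (E, S, SE, SW offsets)
  offs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (o in offs) {
    rr <- px[, 1] + o[1]; cc <- px[, 2] + o[2]
    ok <- rr >= 1 & rr <= nrow(crop) & cc >= 1 & cc <= ncol(crop)
    j <- integer(n); j[ok] <- idx[cbind(rr[ok], cc[ok])]
    hit <- which(j > 0)
    from <- c(from, hit); to <- c(to, j[hit]); wt <- c(wt, rep(o[3], length(hit)))
  }
  # drop diagonal edges shortcut-able through an axial common neighbour,
  # so lengths are not double counted at staircase corners
  keep <- rep(TRUE, length(from))
  diag_e <- which(wt > 1)
  if (length(diag_e) > 0) {
    adj4 <- function(i) {
      rr <- px[i, 1] + c(-1L, 1L, 0L, 0L); cc <- px[i, 2] + c(0L, 0L, -1L, 1L)
      ok <- rr >= 1 & rr <= nrow(crop) & cc >= 1 & cc <= ncol(crop)
      setdiff(unique(idx[cbind(rr[ok], cc[ok])]), 0L)
    }
    for (k in diag_e) {
      if (length(intersect(adj4(from[k]), adj4(to[k]))) > 0) keep[k] <- FALSE
    }
  }
  from <- from[keep]; to <- to[keep]; wt <- wt[keep]
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- wt
  deg <- igraph::degree(g)
  endpoints <- px[deg == 1, , drop = FALSE]
  branch_points <- px[deg >= 3, , drop = FALSE]
  total_length <- sum(wt)
  # longest geodesic between endpoints (or graph diameter for cycles)
  lp_idx <- longest_path_idx(g, which(deg == 1))
  sk <- list(pixels = px, endpoints = endpoints, branch_points = branch_points,
             total_length = total_length,
             longest_path = px[lp_idx, , drop = FALSE], n_pixels = n)
  class(sk) <- "grain_skeleton"
  sk
}

longest_path_idx <- function(g, ends) {
  if (length(ends) >= 2) {
    d <- igraph::distances(g, v = ends, to = ends)
    d[!is.finite(d)] <- -1
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    sp <- igraph::shortest_paths(g, from = ends[ij[1]], to = ends[ij[2]])
    return(as.integer(sp$vpath[[1]]))
  }
  # cycle or blob without endpoints: use the weighted diameter path
  as.integer(igraph::get_diameter(g))
}

#' @export
print.grain_skeleton <- function(x, ...) {
  cat(sprintf("<grain_skeleton> %d px, length %.1f px, %d endpoint(s), %d branch point(s)\n",
              x$n_pixels, x$total_length, nrow(x$endpoints), nrow(x$branch_points)))
  invisible(x)
}

#' Estimate a region's short axis from its skeleton
#'
#' At every skeleton pixel the local grain width is twice the Euclidean
#' distance to the nearest background pixel; the short axis \code{X} is the
#' maximum width over the skeleton. For a single convex grain this equals
#' its minor-axis width; for an adhesion cluster it is the width at the
#' widest grain, which is what the erosion extent should scale with.
#'
#' @param region_mask Integer 0/1 matrix holding one region (other regions,
#'   if present, are treated as foreground obstacles and should be absent).
#' @param skel A \code{grain_skeleton} for that region, in the same
#'   coordinate frame as \code{region_mask}.
#' @return List with elements \code{X} (px), \code{argmax_point}
#'   (row, col) and \code{per_point_widths}.
#' @export
estimate_short_axis <- function(region_mask, skel) {
  stopifnot(sum(region_mask) > 0, nrow(skel$pixels) > 0)
  dm <- distmap_bg(region_mask)
  widths <- 2 * dm[skel$pixels]
  i <- which.max(widths)
  list(X = widths[i], argmax_point = skel$pixels[i, ],
       per_point_widths = widths)
}

#' Erosion extent from the short axis
#'
#' The separation step erodes each region with a disk whose radius is a
#' fixed fraction \code{w} of the region's short axis \code{X}:
#' \code{e = w * X}, rounded to the nearest integer and floored at 1 px.
#'
#' @param X Region short axis in px (> 0).
#' @param w Scale coefficient in (0, 1); default 0.4.
#' @return Integer erosion extent \code{e >= 1} in px.
#' @export
erosion_extent <- function(X, w = 0.4) {
  stopifnot(X > 0, w > 0, w < 1)
  max(1L, as.integer(floor(w * X + 0.5)))
}

#' Split grain adhesions by short-axis-scaled erosion
#'
#' Each 8-connected region is eroded independently by a Euclidean disk of
#' radius [erosion_extent()] of its own short axis (implemented by
#' thresholding the region's distance transform at the extent, which is
#' exact disk erosion). Necks between touching grains are thinner than
#' the grain cores, so erosion removes them and the region falls apart
#' into one fragment per grain. At the default \code{w = 0.4} the radius
#' is 0.4 of the short axis, just under the 0.5 half-width at which a
#' grain's core would disappear: grains shrink hard but survive, while
#' larger coefficients start deleting whole grains — which is why 0.4 is
#' the sweet spot of the coefficient sweep. A vanish guard halves the
#' extent until at least one pixel of the region survives.
#'
#' @param mask Binarized, noise-filtered 0/1 matrix.
#' @param cfg A [grain_config()]; uses \code{cfg$w}.
#' @return 0/1 matrix of eroded fragments. The component count never
#'   decreases and the foreground area never increases.
#' @export
separate <- function(mask, cfg = grain_config()) {
  if (!any(mask == 1L)) return(mask)
  lab <- label_components(mask, 8L)
  nlab <- max(lab)
  dm <- distmap_bg(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  skels <- skeletonize(mask)
  plist <- label_pixels(lab)
  for (i in seq_len(nlab)) {
    pix <- plist[[as.character(i)]]
    widths <- 2 * dm[skels[[i]]$pixels]
    X <- max(widths)
    e <- erosion_extent(X, cfg$w)
    d <- dm[pix]
    repeat {
      kept <- pix[d > e]
      if (length(kept) > 0) break
      e <- e / 2
      if (e < 0.5) {  # last resort: keep the deepest pixel(s)
        kept <- pix[d >= max(d)]
        break
      }
    }
    # discretization guard: the threshold contour is jagged, so slivers
    # with depth barely above e can detach from the core. A real core has
    # interior depth of at least e + 1 px; keep those fragments, or the
    # deepest fragment when none reaches that margin.
    out[core_fragments(kept, dm, e, nrow(mask))] <- 1L
  }
  out
}

core_fragments <- function(kept, dm, e, nr) {
  rc <- decode_rc(kept, nr)
  rr <- range(rc[, 1]); cr <- range(rc[, 2])
  crop <- matrix(0L, rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
  lrc <- cbind(rc[, 1] - rr[1] + 1L, rc[, 2] - cr[1] + 1L)
  crop[lrc] <- 1L
  fl <- label_components(crop, 8L)
  fid <- fl[lrc]
  depth <- dm[kept]
  peak <- tapply(depth, fid, max)
  good <- as.integer(names(peak)[peak >= e + 1])
  if (length(good) == 0) {
    good <- fid[which.max(depth)]
  }
  kept[fid %in% good]
}
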