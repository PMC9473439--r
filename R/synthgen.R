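# Seeded synthetic grain scenes with exact ground truth: dark convex grains
# (ellipse / wedge / round silhouettes with real crop proportions) scattered
# on near-white paper, with controllable pairwise adhesion.

#' Crop silhouette presets
#'
#' Length/width proportions (mm) of the six crops the counter was designed
#' around. \code{wedge} is an ellipse clipped by a chord at 70% of its
#' major axis (one flat end), the silhouette a corn kernel presents;
#' \code{round} is a circle.
#'
#' @param name Optional preset name; omit for the full table.
#' @return A tibble (or single row) with \code{name}, \code{shape},
#'   \code{length_mm}, \code{width_mm}, \code{intensity_mean},
#'   \code{intensity_sd} (8-bit units).
#' @export
grain_presets <- function(name = NULL) {
  tab <- tibble::tibble(
    name = c("wheat", "corn", "mung", "soybean", "peanut", "rape"),
    shape = c("ellipse", "wedge", "ellipse", "ellipse", "ellipse", "round"),
    length_mm = c(7.2, 11.8, 5.5, 11.1, 13, 2.1),
    width_mm = c(3.4, 8.8, 3.9, 6.9, 8, 2.1),
    intensity_mean = c(95, 110, 70, 100, 85, 35),
    intensity_sd = c(8, 8, 8, 8, 8, 5)
  )
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, ]
  if (nrow(row) == 0) stop("unknown preset: ", name)
  row
}

# ellipse radial support in direction theta (relative to orientation phi)
ellipse_radius <- function(A, B, theta, phi) {
  d <- theta - phi
  A * B / sqrt((B * cos(d))^2 + (A * sin(d))^2)
}

# 2x2-supersampled coverage of one grain over its bounding box
render_alpha <- function(shape, cr, cc, A, B, phi, rows, cols) {
  offs <- c(-0.25, 0.25)
  acc <- matrix(0, length(rows), length(cols))
  cphi <- cos(phi); sphi <- sin(phi)
  for (or in offs) for (oc in offs) {
    dr <- outer(rows + or - cr, rep(1, length(cols)))
    dc <- outer(rep(1, length(rows)), cols + oc - cc)
    u <- dc * cphi + dr * sphi       # along major axis
    v <- -dc * sphi + dr * cphi      # along minor axis
    inside <- (u / A)^2 + (v / B)^2 <= 1
    if (shape == "wedge") inside <- inside & (u <= 0.4 * A)
    acc <- acc + inside
  }
  acc / 4
}

# grain geometry in px for a preset at a scale
grain_geom <- function(preset, px_per_mm) {
  L <- preset$length_mm * px_per_mm
  W <- preset$width_mm * px_per_mm
  if (preset$shape == "wedge") {
    A <- L / 1.4       # clipped at u = 0.4 A, so length = 1.4 A
  } else {
    A <- L / 2
  }
  list(A = A, B = W / 2, shape = preset$shape, length_px = L, width_px = W)
}

#' Generate a synthetic grain scene with exact ground truth
#'
#' Places \code{n} grains of one crop preset at uniform random positions
#' and orientations on a near-white canvas, renders them with 2x2
#' supersampled anti-aliasing, per-grain intensity jitter, Gaussian pixel
#' noise and an optional linear illumination gradient, and returns the
#' image together with the full ground truth. A fraction
#' \code{adhesion_frac} of the grains is laid out in touching pairs and
#' triples whose overlap depth along the contact line is
#' \code{overlap_depth_frac} times the grain width; all other grains keep
#' a guaranteed clearance of \code{gap_px}, so the true cluster count is
#' known by construction. Rendering is bit-reproducible from
#' \code{(seed, parameters)}.
#'
#' @param n Number of grains (>= 1).
#' @param preset Preset name (see [grain_presets()]) or a one-row preset
#'   tibble.
#' @param adhesion_frac Fraction of grains placed in touching clusters.
#' @param overlap_depth_frac Overlap depth as a fraction of grain width.
#' @param canvas Canvas size, c(height, width) px.
#' @param seed Integer seed.
#' @param px_per_mm Pixel scale; \code{NULL} auto-fits so silhouettes fill
#'   about 15% of the canvas, capped at 10 px/mm.
#' @param background_mean Paper intensity, 8-bit units.
#' @param noise_sd Pixel noise standard deviation, 8-bit units.
#' @param gradient Peak-to-peak amplitude of a left-to-right illumination
#'   gradient, 8-bit units (0 disables).
#' @param gap_px Minimum clearance between distinct objects, px.
#' @param max_retries Placement attempts per grain before giving up.
#' @return A \code{synthetic_scene}: list with \code{image} (matrix in
#'   \[0, 1\]), \code{truth} tibble (one row per grain: centre, semi-axes,
#'   orientation, shape, cluster id, intensity), \code{N1},
#'   \code{adhesion_pairs}, \code{n_clusters}, \code{truth_mask},
#'   \code{seed}, \code{background_mean}, \code{px_per_mm}.
#' @export
generate_scene <- function(n, preset = "wheat", adhesion_frac = 0,
                           overlap_depth_frac = 0.2,
                           canvas = c(1440, 1920), seed = 1,
                           px_per_mm = NULL, background_mean = 245,
                           noise_sd = 4, gradient = 5, gap_px = 6,
                           max_retries = 400) {
  stopifnot(n >= 1, adhesion_frac >= 0, adhesion_frac <= 1)
  if (is.character(preset)) preset <- grain_presets(preset)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  if (is.null(px_per_mm)) {
    sil_mm2 <- pi * (preset$length_mm / 2) * (preset$width_mm / 2)
    px_per_mm <- min(10, sqrt(0.15 * prod(canvas) / (n * sil_mm2)))
  }
  geom <- grain_geom(preset, px_per_mm)
  A <- geom$A; B <- geom$B
  rmax <- max(A, B)

  # cluster plan: sizes of touching groups summing to ~adhesion_frac * n
  n_adh <- round(adhesion_frac * n)
  sizes <- integer(0)
  left <- n_adh
  while (left >= 2) {
    s <- if (left >= 3 && runif(1) < 0.3) 3L else 2L
    sizes <- c(sizes, s)
    left <- left - s
  }
  n_singles <- n - sum(sizes)

  occupancy <- matrix(FALSE, canvas[1], canvas[2])
  truth <- list()
  adhesion_pairs <- list()
  gid <- 0L
  cluster_id <- 0L
  margin <- rmax + 2

  stamp <- function(sil, rows, cols) {
    occupancy[rows, cols] <<- occupancy[rows, cols] | sil
  }
  grain_sil <- function(cr, cc, phi, enlarge = 0) {
    rows <- max(1, floor(cr - rmax - enlarge)):min(canvas[1], ceiling(cr + rmax + enlarge))
    cols <- max(1, floor(cc - rmax - enlarge)):min(canvas[2], ceiling(cc + rmax + enlarge))
    a <- render_alpha(geom$shape, cr, cc, A + enlarge, B + enlarge, phi, rows, cols)
    list(sil = a >= 0.5, rows = rows, cols = cols)
  }
  place_free <- function(exclude_occ = occupancy) {
    for (try in seq_len(max_retries)) {
      cr <- runif(1, margin, canvas[1] - margin)
      cc <- runif(1, margin, canvas[2] - margin)
      phi <- runif(1, 0, pi)
      g <- grain_sil(cr, cc, phi, enlarge = gap_px)
      if (!any(g$sil & exclude_occ[g$rows, g$cols])) {
        return(list(cr = cr, cc = cc, phi = phi))
      }
    }
    NULL
  }
  add_grain <- function(cr, cc, phi, cl) {
    gid <<- gid + 1L
    truth[[gid]] <<- tibble::tibble(
      id = gid, center_r = cr, center_c = cc, semi_major = A, semi_minor = B,
      orientation = phi, shape = geom$shape, cluster = cl,
      intensity = max(5, rnorm(1, preset$intensity_mean, preset$intensity_sd)))
    g <- grain_sil(cr, cc, phi)
    stamp(g$sil, g$rows, g$cols)
    gid
  }

  # clusters first (they are hardest to place), then singles
  for (s in sizes) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      anchor <- place_free()
      if (is.null(anchor)) break
      members <- list(anchor)
      ok <- TRUE
      for (k in seq_len(s - 1)) {
        prev <- members[[k]]
        part <- NULL
        for (t2 in seq_len(max_retries)) {
          theta <- runif(1, 0, 2 * pi)
          phi2 <- runif(1, 0, pi)
          depth <- overlap_depth_frac * geom$width_px
          dist <- ellipse_radius(A, B, theta, prev$phi) +
                  ellipse_radius(A, B, theta + pi, phi2) - depth
          cr2 <- prev$cr + dist * sin(theta)
          cc2 <- prev$cc + dist * cos(theta)
          if (cr2 < margin || cr2 > canvas[1] - margin ||
              cc2 < margin || cc2 > canvas[2] - margin) next
          g2 <- grain_sil(cr2, cc2, phi2, enlarge = gap_px)
          if (any(g2$sil & occupancy[g2$rows, g2$cols])) next
          # must actually touch/overlap every intended mate's silhouette
          s2 <- grain_sil(cr2, cc2, phi2, enlarge = 1)
          sp <- grain_sil(prev$cr, prev$cc, prev$phi)
          common_r <- intersect(s2$rows, sp$rows)
          common_c <- intersect(s2$cols, sp$cols)
          if (length(common_r) == 0 || length(common_c) == 0) next
          t1 <- s2$sil[match(common_r, s2$rows), match(common_c, s2$cols), drop = FALSE]
          t0 <- sp$sil[match(common_r, sp$rows), match(common_c, sp$cols), drop = FALSE]
          if (!any(t1 & t0)) next
          part <- list(cr = cr2, cc = cc2, phi = phi2)
          break
        }
        if (is.null(part)) { ok <- FALSE; break }
        members[[k + 1]] <- part
      }
      if (!ok) next
      cluster_id <- cluster_id + 1L
      ids <- integer(s)
      for (k in seq_len(s)) {
        m <- members[[k]]
        ids[k] <- add_grain(m$cr, m$cc, m$phi, cluster_id)
      }
      for (k in seq_len(s - 1)) {
        adhesion_pairs[[length(adhesion_pairs) + 1]] <- c(ids[k], ids[k + 1])
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf("could not place adhesion cluster; placed %d of %d grains",
                   gid, n))
    }
  }
  for (k in seq_len(n_singles)) {
    p <- place_free()
    if (is.null(p)) {
      stop(sprintf("could not place grain %d of %d within retry budget",
                   gid + 1L, n))
    }
    cluster_id <- cluster_id + 1L
    add_grain(p$cr, p$cc, p$phi, cluster_id)
  }
  truth <- do.call(rbind, truth)

  # render: paper + gradient + grains + pixel noise, 8-bit quantized
  img <- matrix(background_mean / 255, canvas[1], canvas[2])
  if (gradient > 0) {
    img <- img + outer(rep(1, canvas[1]),
                       seq(-gradient / 2, gradient / 2,
                           length.out = canvas[2]) / 255)
  }
  truth_mask <- matrix(FALSE, canvas[1], canvas[2])
  for (i in seq_len(nrow(truth))) {
    g <- truth[i, ]
    rows <- max(1, floor(g$center_r - rmax)):min(canvas[1], ceiling(g$center_r + rmax))
    cols <- max(1, floor(g$center_c - rmax)):min(canvas[2], ceiling(g$center_c + rmax))
    a <- render_alpha(g$shape, g$center_r, g$center_c, g$semi_major,
                      g$semi_minor, g$orientation, rows, cols)
    img[rows, cols] <- img[rows, cols] * (1 - a) + (g$intensity / 255) * a
    truth_mask[rows, cols] <- truth_mask[rows, cols] | (a >= 0.5)
  }
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, noise_sd / 255),
                        nrow(img), ncol(img))
  }
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  structure(list(
    image = img, truth = truth, N1 = nrow(truth),
    adhesion_pairs = adhesion_pairs,
    n_clusters = length(unique(truth$cluster)),
    truth_mask = truth_mask, seed = seed,
    background_mean = background_mean, px_per_mm = px_per_mm,
    preset = preset$name
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s, N1 = %d grains in %d cluster(s), %dx%d px, seed %s\n",
              x$preset, x$N1, x$n_clusters, nrow(x$image), ncol(x$image),
              format(x$seed)))
  invisible(x)
}

#' Write a scene to PNG with a ground-truth JSON sidecar
#'
#' @param scene A \code{synthetic_scene}.
#' @param path Output PNG path; the sidecar is written next to it with a
#'   \code{.json} extension.
#' @return \code{path}, invisibly.
#' @export
write_scene <- function(scene, path) {
  png::writePNG(scene$image, path)
  sidecar <- sub("\\.png$", ".json", path)
  jsonlite::write_json(list(
    N1 = scene$N1, seed = scene$seed, preset = scene$preset,
    px_per_mm = scene$px_per_mm, background_mean = scene$background_mean,
    n_clusters = scene$n_clusters,
    truth = scene$truth[, c("id", "center_r", "center_c", "semi_major",
                            "semi_minor", "orientation", "shape", "cluster")]
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The near-collinear two-grain fixture
#'
#' Two identical ellipse grains overlapped almost end-to-end (major axes
#' within 5 degrees of collinear), with the overlap tuned so only one
#' concave junction corner survives on the boundary — the configuration
#' where the corner formula returns 1.5 and the linear-adhesion rule must
#' step in. True count: 2.
#'
#' @return A \code{synthetic_scene} with \code{N1 = 2}.
#' @export
render_collinear_fixture <- function() {
  canvas <- c(160, 260)
  A <- 30; B <- 12
  g <- tibble::tibble(
    id = 1:2,
    center_r = c(80, 80 + 3),
    center_c = c(95, 95 + 52),
    semi_major = A, semi_minor = B,
    orientation = c(0.0, -5 * pi / 180),
    shape = "ellipse", cluster = 1L,
    intensity = 70
  )
  img <- matrix(245 / 255, canvas[1], canvas[2])
  truth_mask <- matrix(FALSE, canvas[1], canvas[2])
  for (i in 1:2) {
    rows <- 1:canvas[1]; cols <- 1:canvas[2]
    a <- render_alpha("ellipse", g$center_r[i], g$center_c[i], A, B,
                      g$orientation[i], rows, cols)
    img <- img * (1 - a) + (70 / 255) * a
    truth_mask <- truth_mask | (a >= 0.5)
  }
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  structure(list(image = img, truth = g, N1 = 2L,
                 adhesion_pairs = list(c(1L, 2L)), n_clusters = 1L,
                 truth_mask = truth_mask, seed = NA_integer_,
                 background_mean = 245, px_per_mm = NA_real_,
                 preset = "collinear-pair"), class = "synthetic_scene")
}
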