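# Accuracy metrics and the benchmark / coefficient-sweep harness.

#' Correct ratio (percent)
#'
#' \eqn{CR = (1 - |N_1 - N_2| / N_1) \times 100}, where \eqn{N_1} is the
#' true grain count and \eqn{N_2} the algorithm's count. The absolute
#' value keeps over- and under-counts symmetric, so \eqn{CR \le 100}.
#'
#' @param N1 True count (> 0).
#' @param N2 Algorithm count (>= 0).
#' @return Percent.
#' @export
correct_ratio <- function(N1, N2) {
  stopifnot(all(N1 > 0), all(N2 >= 0))
  (1 - abs(N1 - N2) / N1) * 100
}

#' Error ratio (percent)
#'
#' \eqn{ER = |N_1 - N_2| / N_1 \times 100}; the exact complement of
#' [correct_ratio()], so \code{CR + ER == 100} for every input.
#'
#' @inheritParams correct_ratio
#' @return Percent.
#' @export
error_ratio <- function(N1, N2) {
  stopifnot(all(N1 > 0), all(N2 >= 0))
  abs(N1 - N2) / N1 * 100
}

#' Mean accuracy and volatility of a series of per-scene accuracies
#'
#' \eqn{M} is the arithmetic mean of the accuracies and \eqn{s^2} their
#' population variance (divisor \eqn{n}, not \eqn{n - 1}); the harness
#' conventionally uses series of 8 count levels (50 to 400 grains in
#' steps of 50) but any non-empty series is accepted.
#'
#' @param xs Numeric vector of accuracies (percent), non-empty.
#' @return List with \code{M} (mean, percent) and \code{s2} (population
#'   variance, percent^2).
#' @export
volatility <- function(xs) {
  stopifnot(length(xs) >= 1)
  M <- mean(xs)
  list(M = M, s2 = mean((xs - M)^2))
}

#' Built-in counting backends for benchmarking
#'
#' \code{backend_pipeline} is the full counter ([count_image()]).
#' \code{backend_global_erosion} is the classical baseline: one fixed
#' erosion of the whole mask by a disk scaled to the median region short
#' axis, then a component count — no per-region adaptation, no corner
#' formula. Each backend maps a binarized mask to a total count.
#'
#' @param mask 0/1 matrix.
#' @param cfg A [grain_config()].
#' @return Integer count.
#' @export
backend_pipeline <- function(mask, cfg = grain_config()) {
  count_image(mask, cfg)$total
}

#' @rdname backend_pipeline
#' @export
backend_global_erosion <- function(mask, cfg = grain_config()) {
  mask <- drop_small_components(mask, cfg$min_blob_area)
  if (!any(mask == 1L)) return(0L)
  regions <- label_components(mask, 8L)
  dm <- distmap_bg(mask)
  plist <- label_pixels(regions)
  X <- median(vapply(plist, function(p) 2 * max(dm[p]), numeric(1)))
  e <- erosion_extent(X, cfg$w)
  eroded <- matrix(0L, nrow(mask), ncol(mask))
  eroded[dm > e] <- 1L
  max(label_components(eroded, 8L))
}

#' Benchmark counting backends on synthetic scenes
#'
#' Binarizes each scene once and hands the mask to every backend; correct
#' and error ratios are computed against the scene's ground truth. A
#' backend failure on a scene is recorded as \code{NA} and the run
#' continues.
#'
#' @param scenes List of \code{synthetic_scene} objects.
#' @param methods Named list of backend functions
#'   \code{function(mask, cfg) -> count}; defaults to the full pipeline
#'   and the global-erosion baseline.
#' @param cfg A [grain_config()].
#' @return Tibble with columns \code{scene_id}, \code{seed},
#'   \code{n_true}, \code{method}, \code{n_est}, \code{CR}, \code{ER}.
#' @export
run_benchmark <- function(scenes,
                          methods = list(pipeline = backend_pipeline,
                                         global_erosion = backend_global_erosion),
                          cfg = grain_config()) {
  rows <- list()
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    mask <- binarize(sc$image, cfg)
    for (mi in seq_along(methods)) {
      n_est <- tryCatch(suppressWarnings(methods[[mi]](mask, cfg)),
                        error = function(e) NA_integer_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        scene_id = si, seed = sc$seed, n_true = sc$N1,
        method = names(methods)[mi], n_est = as.integer(n_est),
        CR = if (is.na(n_est)) NA_real_ else correct_ratio(sc$N1, n_est),
        ER = if (is.na(n_est)) NA_real_ else error_ratio(sc$N1, n_est))
    }
  }
  do.call(rbind, rows)
}

#' The standard adhesion benchmark for the erosion-coefficient sweep
#'
#' Twelve scenes — each crop preset at a shallow (0.15) and a deep (0.35)
#' overlap, 40 grains per scene with 60% of them in touching clusters on
#' a 720x960 canvas — generated deterministically from \code{seed}.
#'
#' @param seed Integer seed.
#' @return List of \code{synthetic_scene} objects.
#' @export
adhesion_benchmark <- function(seed = 1) {
  presets <- grain_presets()$name
  scenes <- list()
  i <- 0
  for (depth in c(0.15, 0.35)) {
    for (p in presets) {
      i <- i + 1
      scenes[[i]] <- generate_scene(
        n = 40, preset = p, adhesion_frac = 0.6,
        overlap_depth_frac = depth, canvas = c(720, 960),
        seed = seed * 500 + i)
    }
  }
  scenes
}

#' Sweep the erosion scale coefficient
#'
#' For every \code{w} in the grid, runs the separation step on each
#' benchmark scene and scores the fraction of grains correctly isolated:
#' a grain counts as isolated when its centre falls in a surviving
#' fragment that contains no other grain's centre (under-erosion leaves
#' several grains in one fragment, over-erosion deletes grains entirely).
#'
#' @param scenes List of \code{synthetic_scene} objects, e.g.
#'   [adhesion_benchmark()].
#' @param ws Coefficient grid.
#' @param cfg A [grain_config()] (its \code{w} is overridden).
#' @return Tibble with \code{w} and \code{isolated_frac} (mean over
#'   scenes).
#' @export
sweep_w <- function(scenes, ws = seq(0.1, 0.9, by = 0.1),
                    cfg = grain_config()) {
  masks <- lapply(scenes, function(sc) binarize(sc$image, cfg))
  rows <- lapply(ws, function(wv) {
    cfgw <- cfg
    cfgw$w <- wv
    fr <- vapply(seq_along(scenes), function(si) {
      sep <- separate(masks[[si]], cfgw)
      isolation_fraction(scenes[[si]], sep)
    }, numeric(1))
    tibble::tibble(w = wv, isolated_frac = mean(fr))
  })
  do.call(rbind, rows)
}

# fraction of true grains whose centre lies in a fragment holding no other
# grain centre
isolation_fraction <- function(scene, separated_mask) {
  labs <- label_components(separated_mask, 8L)
  ctr <- cbind(pmin(pmax(round(scene$truth$center_r), 1), nrow(labs)),
               pmin(pmax(round(scene$truth$center_c), 1), ncol(labs)))
  at <- labs[ctr]
  ok <- at > 0
  shared <- at %in% at[duplicated(at) & at > 0]
  mean(ok & !shared)
}

#' The standard accuracy-recovery scene set
#'
#' Twenty scenes spanning the agricultural counting range (50 to 400
#' grains in steps of 50), cycling through the six crop presets and
#' adhesion fractions 0, 0.1, 0.2, 0.3 at overlap depth 0.2.
#'
#' @param seed Integer seed.
#' @return List of \code{synthetic_scene} objects.
#' @export
recovery_scenes <- function(seed = 1) {
  ns <- seq(50, 400, by = 50)
  presets <- grain_presets()$name
  adh <- c(0, 0.1, 0.2, 0.3)
  lapply(seq_len(20), function(i) {
    generate_scene(
      n = ns[(i - 1) %% 8 + 1],
      preset = presets[(i - 1) %% 6 + 1],
      adhesion_frac = adh[(i - 1) %% 4 + 1],
      overlap_depth_frac = 0.2,
      seed = seed * 1000 + i)
  })
}
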