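#' Pipeline configuration
#'
#' Bundles every tunable parameter of the counting pipeline. Defaults are
#' the values the method was developed with: photographs compressed to a
#' 1920-px long side, 5x5 Gaussian denoising before Otsu thresholding, an
#' erosion extent of \code{w = 0.4} times the region short axis, a 13x13
#' corner window with a 0.66 foreground-fraction threshold, and the
#' linear-adhesion rule (skeleton longer than 1.5x the image mean with an
#' included angle between 160 and 200 degrees).
#'
#' @param target_long_side Long-side resolution photographs are downscaled
#'   to before processing (px). Images already smaller are left untouched.
#' @param gaussian_kernel Odd side length of the Gaussian denoising kernel
#'   (px).
#' @param gaussian_sigma Gaussian sigma; \code{0} derives it from the
#'   kernel size (\code{0.3 * ((k - 1)/2 - 1) + 0.8}, the usual convention).
#' @param w Erosion scale coefficient: each region is eroded by a disk of
#'   radius \code{w * X} where \code{X} is the region's short axis.
#'   Must lie strictly between 0 and 1; seed cores survive while
#'   \code{w} stays below the half-width coefficient 0.5.
#' @param corner_window Odd side length (px) of the window whose foreground
#'   fraction scores boundary pixels as corner candidates.
#' @param corner_fraction Fraction threshold a boundary pixel must exceed
#'   (strictly) to be a corner candidate.
#' @param length_factor A region is considered for the linear-adhesion rule
#'   when its skeleton is longer than \code{length_factor} times the mean
#'   skeleton length over the image.
#' @param angle_band Two-element numeric vector (degrees): the clockwise
#'   included angle at the skeleton midpoint must fall inside this band for
#'   the linear-adhesion rule to fire.
#' @param min_blob_area Connected components smaller than this (px^2) are
#'   discarded as noise after binarization.
#' @param random_seed Integer seed recorded with results; \code{NA} for
#'   none. The counting pipeline itself is deterministic.
#'
#' @return An object of class \code{grain_config} (a named list).
#' @examples
#' cfg <- grain_config()
#' cfg$w
#' @export
grain_config <- function(target_long_side = 1920,
                         gaussian_kernel = 5,
                         gaussian_sigma = 0,
                         w = 0.4,
                         corner_window = 13,
                         corner_fraction = 0.66,
                         length_factor = 1.5,
                         angle_band = c(160, 200),
                         min_blob_area = 9,
                         random_seed = NA_integer_) {
  cfg <- list(
    target_long_side = as.numeric(target_long_side),
    gaussian_kernel = as.integer(gaussian_kernel),
    gaussian_sigma = as.numeric(gaussian_sigma),
    w = as.numeric(w),
    corner_window = as.integer(corner_window),
    corner_fraction = as.numeric(corner_fraction),
    length_factor = as.numeric(length_factor),
    angle_band = as.numeric(angle_band),
    min_blob_area = as.numeric(min_blob_area),
    random_seed = random_seed
  )
  class(cfg) <- "grain_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$target_long_side >= 1,
    cfg$gaussian_kernel >= 1, cfg$gaussian_kernel %% 2 == 1,
    cfg$w > 0, cfg$w < 1,
    cfg$corner_window >= 3, cfg$corner_window %% 2 == 1,
    cfg$corner_fraction > 0, cfg$corner_fraction < 1,
    length(cfg$angle_band) == 2,
    all(cfg$angle_band >= 0), all(cfg$angle_band <= 360),
    cfg$length_factor > 0,
    cfg$min_blob_area >= 0
  )
  invisible(cfg)
}

#' @export
print.grain_config <- function(x, ...) {
  cat("<grain_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to a YAML file whose keys are \code{grain_config}
#'   argument names.
#' @return A \code{grain_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(grain_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(grain_config, vals)
}

# effective Gaussian sigma for a kernel size
effective_sigma <- function(cfg) {
  if (cfg$gaussian_sigma > 0) return(cfg$gaussian_sigma)
  k <- cfg$gaussian_kernel
  0.3 * ((k - 1) / 2 - 1) + 0.8
}

# stable hash of the configuration for run logs
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 12), collapse = ","), ""), collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  substr(unname(tools::md5sum(f)), 1, 8)
}
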