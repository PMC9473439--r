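# Result display and structured output: the red-dot / yellow-number
# annotation convention, tidy accessors, JSON/CSV writers.

#' Total grain count implied by an annotation
#'
#' The display convention marks every counting unit with a red dot; units
#' holding two or more grains additionally carry a yellow count at the
#' dot's upper right, and such dots are excluded from the dot tally. The
#' image total is the number of unlabelled dots plus the sum of the
#' yellow numbers.
#'
#' @param ann Annotation tibble (\code{row}, \code{col}, \code{count},
#'   \code{labeled}) as found in \code{grain_count$annotations}, or a
#'   list with elements \code{dots} (n x 2 matrix) and
#'   \code{adhesion_labels} (list of \code{list(position=, count=)}).
#' @return Integer total.
#' @export
total_from_annotation <- function(ann) {
  if (is.data.frame(ann)) {
    return(as.integer(sum(!ann$labeled) + sum(ann$count[ann$labeled])))
  }
  n_dots <- if (is.null(ann$dots)) 0L else nrow(ann$dots)
  n_lab <- length(ann$adhesion_labels)
  as.integer((n_dots - n_lab) +
               sum(vapply(ann$adhesion_labels,
                          function(l) as.integer(l$count), integer(1))))
}

# 3x5 bitmap digit glyphs for annotation labels
digit_glyphs <- function() {
  g <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(g, function(rows) {
    do.call(rbind, lapply(strsplit(rows, ""), function(r) as.integer(r == "1")))
  })
}

#' Annotate an image with counting results
#'
#' Returns a copy of the image with a red dot at every counting unit's
#' centroid and, for units counted as two or more grains, a yellow count
#' rendered at the dot's upper right (the dot then marks an adhesion
#' area, not a single grain). Centroids outside the image are skipped
#' with a warning.
#'
#' @param img Image array (grayscale matrix or RGB array) in \[0, 1\].
#' @param result A \code{grain_count} object.
#' @param dot_radius Dot radius in px.
#' @param text_scale Integer scale factor of the 3x5 digit font.
#' @return Height x width x 3 RGB array.
#' @export
annotate_image <- function(img, result, dot_radius = 4, text_scale = 3) {
  if (is.matrix(img)) {
    rgb <- array(rep(img, 3), c(dim(img), 3))
  } else {
    rgb <- img
  }
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  glyphs <- digit_glyphs()
  set_px <- function(rr, cc, col) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    for (ch in 1:3) {
      pl <- rgb[, , ch]
      pl[cbind(rr[ok], cc[ok])] <- col[ch]
      rgb[, , ch] <<- pl
    }
  }
  ann <- result$annotations
  for (i in seq_len(nrow(ann))) {
    r0 <- round(ann$row[i]); c0 <- round(ann$col[i])
    if (r0 < 1 || r0 > h || c0 < 1 || c0 > w) {
      warning(sprintf("annotation centroid (%d, %d) outside image, skipped",
                      r0, c0))
      next
    }
    dd <- expand.grid(dr = -dot_radius:dot_radius, dc = -dot_radius:dot_radius)
    dd <- dd[dd$dr^2 + dd$dc^2 <= dot_radius^2, ]
    set_px(r0 + dd$dr, c0 + dd$dc, c(1, 0, 0))
    if (ann$labeled[i]) {
      digits <- strsplit(as.character(ann$count[i]), "")[[1]]
      cx <- c0 + dot_radius + 2
      top <- r0 - dot_radius - 5 * text_scale - 1
      for (d in digits) {
        gl <- glyphs[[d]]
        gl <- gl[rep(seq_len(5), each = text_scale),
                 rep(seq_len(3), each = text_scale)]
        on <- which(gl == 1L, arr.ind = TRUE)
        set_px(top + on[, 1] - 1, cx + on[, 2] - 1, c(1, 0.85, 0))
        cx <- cx + 3 * text_scale + text_scale
      }
    }
  }
  rgb
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a grain count: one row per counting unit
#'
#' @param x A \code{grain_count}.
#' @param ... Unused.
#' @return The per-unit tibble (centroid, area, corners, holes, raw and
#'   corrected counts, method).
#' @method tidy grain_count
#' @export
tidy.grain_count <- function(x, ...) x$regions

#' One-row summary of a grain count
#'
#' @param x A \code{grain_count}.
#' @param ... Unused.
#' @return Tibble with the total, unit counts per method and the mean
#'   single-grain area.
#' @method glance grain_count
#' @export
glance.grain_count <- function(x, ...) {
  tibble::tibble(
    total = x$total,
    n_units = nrow(x$regions),
    n_single = sum(x$regions$method == "single"),
    n_corner_formula = sum(x$regions$method == "corner_formula"),
    n_average_area = sum(x$regions$method == "average_area"),
    mean_single_area = x$mean_single_area)
}

#' Plot a grain count
#'
#' Shows the processed image with the red-dot / yellow-number annotation
#' convention as a ggplot.
#'
#' @param object A \code{grain_count} (ideally from [count_grains()], so
#'   the processed image is attached).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grain_count
#' @export
autoplot.grain_count <- function(object, ...) {
  ann <- object$annotations
  h <- object$img_dim[1]; w <- object$img_dim[2]
  df <- tibble::tibble(x = ann$col, y = h - ann$row + 1,
                       label = ifelse(ann$labeled, as.character(ann$count), ""),
                       kind = ifelse(ann$labeled, "adhesion", "single"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y))
  img <- attr(object, "image")
  if (!is.null(img)) {
    if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
    p <- p + ggplot2::annotation_raster(grDevices::as.raster(img),
                                        xmin = 1, xmax = w, ymin = 1, ymax = h)
  }
  p + ggplot2::geom_point(colour = "red", size = 1.6) +
    ggplot2::geom_text(ggplot2::aes(label = label), colour = "gold3",
                       nudge_x = w / 80, nudge_y = h / 80, size = 3) +
    ggplot2::coord_fixed(xlim = c(1, w), ylim = c(1, h), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d grains", object$total)) +
    ggplot2::theme_void()
}

#' Write a grain count as JSON or CSV
#'
#' JSON carries the total, the per-unit records, the configuration and a
#' schema version; CSV holds one row per counting unit. Both agree on
#' every per-unit count.
#'
#' @param result A \code{grain_count}.
#' @param path Output path.
#' @param truth Optional true count; when given, correct and error ratios
#'   are included.
#' @return \code{path}, invisibly.
#' @export
write_result_json <- function(result, path, truth = NULL) {
  out <- list(
    version = "1",
    total = result$total,
    mean_single_area = result$mean_single_area,
    regions = result$regions[, setdiff(names(result$regions), c("bbox"))],
    config = unclass(result$config),
    config_hash = config_hash(result$config))
  if (!is.null(truth)) {
    out$truth <- truth
    out$CR <- correct_ratio(truth, result$total)
    out$ER <- error_ratio(truth, result$total)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_result_json
#' @export
write_result_csv <- function(result, path) {
  utils::write.csv(result$regions, path, row.names = FALSE)
  invisible(path)
}
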