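#' Load a photograph
#'
#' Reads an 8-bit JPEG or PNG photograph into a numeric array with values
#' in \[0, 1\] (a matrix for grayscale, height x width x 3 for colour).
#' An alpha channel, if present, is dropped. For JPEGs carrying an EXIF
#' orientation tag the stored pixels are rotated/mirrored so the returned
#' array matches the display orientation.
#'
#' @param path Path to a JPEG or PNG file.
#' @return Numeric matrix (grayscale) or height x width x 3 array (RGB).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: no such file: ", path)
  }
  magic <- readBin(path, "raw", n = 8)
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47))
  jpg_sig <- as.raw(c(0xff, 0xd8))
  img <- if (length(magic) >= 4 && identical(magic[1:4], png_sig)) {
    tryCatch(png::readPNG(path),
             error = function(e) stop("corrupt PNG file: ", path))
  } else if (length(magic) >= 2 && identical(magic[1:2], jpg_sig)) {
    x <- tryCatch(jpeg::readJPEG(path),
                  error = function(e) stop("corrupt JPEG file: ", path))
    orient_image(x, exif_orientation(path))
  } else {
    stop("unsupported image format (expected JPEG or PNG): ", path)
  }
  drop_alpha(img)
}

drop_alpha <- function(img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 2) return(img[, , 1])          # gray + alpha
    if (dim(img)[3] >= 4) return(img[, , 1:3])
    if (dim(img)[3] == 1) return(img[, , 1])
  }
  img
}

#' @rdname load_image
#' @details \code{exif_orientation} parses the EXIF APP1 segment of a JPEG
#'   and returns the orientation code (1 to 8, or 1 when absent); it is
#'   exported mainly for testing orientation handling.
#' @export
exif_orientation <- function(path) {
  n <- min(file.size(path), 131072)   # orientation lives in the header
  bytes <- readBin(path, "raw", n = n)
  if (length(bytes) < 4) return(1L)
  i <- 3L  # skip SOI
  while (i + 3 <= length(bytes)) {
    if (bytes[i] != as.raw(0xff)) return(1L)
    marker <- as.integer(bytes[i + 1])
    seglen <- as.integer(bytes[i + 2]) * 256L + as.integer(bytes[i + 3])
    if (marker == 0xe1 && i + 9 <= length(bytes) &&
        identical(bytes[(i + 4):(i + 9)],
                  as.raw(c(0x45, 0x78, 0x69, 0x66, 0x00, 0x00)))) {
      tiff0 <- i + 10L  # offset of TIFF header
      if (tiff0 + 7 > length(bytes)) return(1L)
      le <- identical(bytes[tiff0:(tiff0 + 1)], as.raw(c(0x49, 0x49)))
      rd16 <- function(off) {
        a <- as.integer(bytes[off]); b <- as.integer(bytes[off + 1])
        if (le) a + 256L * b else 256L * a + b
      }
      rd32 <- function(off) {
        v <- as.integer(bytes[off:(off + 3)])
        if (le) sum(v * c(1, 256, 65536, 16777216))
        else sum(v * c(16777216, 65536, 256, 1))
      }
      ifd <- tiff0 + rd32(tiff0 + 4L)
      if (ifd + 1 > length(bytes)) return(1L)
      nent <- rd16(ifd)
      for (k in seq_len(nent)) {
        ent <- ifd + 2L + (k - 1L) * 12L
        if (ent + 11 > length(bytes)) return(1L)
        if (rd16(ent) == 0x0112) {
          v <- rd16(ent + 8L)
          if (v >= 1 && v <= 8) return(as.integer(v))
          return(1L)
        }
      }
      return(1L)
    }
    if (marker >= 0xd0 && marker <= 0xda) return(1L)  # into scan data
    i <- i + 2L + seglen
  }
  1L
}

# apply an EXIF orientation code to an image array
orient_image <- function(img, orientation) {
  if (orientation == 1) return(img)
  per_channel <- function(f, x) {
    if (is.matrix(x)) return(f(x))
    out <- NULL
    for (ch in seq_len(dim(x)[3])) {
      y <- f(x[, , ch])
      if (is.null(out)) out <- array(0, c(dim(y), dim(x)[3]))
      out[, , ch] <- y
    }
    out
  }
  flip_h <- function(m) m[, ncol(m):1, drop = FALSE]
  flip_v <- function(m) m[nrow(m):1, , drop = FALSE]
  rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  switch(as.character(orientation),
    "2" = per_channel(flip_h, img),
    "3" = per_channel(function(m) flip_h(flip_v(m)), img),
    "4" = per_channel(flip_v, img),
    "5" = per_channel(function(m) t(m), img),
    "6" = per_channel(rot90cw, img),
    "7" = per_channel(function(m) flip_h(rot90ccw(m)), img),
    "8" = per_channel(rot90ccw, img),
    img)
}

#' Downscale an image so its long side matches a target resolution
#'
#' Photographs straight off a phone camera are much larger than the
#' processing resolution the pipeline was tuned at; this shrinks the image
#' with exact area-average resampling so the long side equals
#' \code{target_long_side} and the short side scales proportionally
#' (rounded to the nearest pixel, minimum 1). Images already at or below
#' the target are returned unchanged — upscaling adds no information and
#' would change the pixel scale of the short-axis estimate.
#'
#' @param img Image array as returned by [load_image()].
#' @param target_long_side Target long-side resolution in px.
#' @return Image array of the resized dimensions.
#' @export
resize_long_side <- function(img, target_long_side = 1920) {
  stopifnot(target_long_side >= 1)
  d <- dim(img)[1:2]
  long <- max(d)
  if (long <= target_long_side) return(img)
  scale <- target_long_side / long
  newd <- pmax(1L, as.integer(round(d * scale)))
  newd[which.max(d)] <- as.integer(target_long_side)
  if (is.matrix(img)) {
    return(resize_area_cpp(img, newd[1], newd[2]))
  }
  out <- array(0, c(newd, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- resize_area_cpp(img[, , ch], newd[1], newd[2])
  }
  out
}

# Rec. 601 luminance
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Binarize a photograph into a grain-foreground mask
#'
#' Converts to grayscale (Rec. 601 luminance), denoises with a Gaussian
#' filter, applies a global Otsu threshold, and picks the grain class
#' automatically: of the two Otsu classes, the one occupying the smaller
#' share of the image border becomes foreground (on a white-paper scene
#' the paper touches the border almost everywhere). Components smaller
#' than \code{cfg$min_blob_area} are removed as noise.
#'
#' If the image is uniform (Otsu degenerate), an empty mask is returned
#' with a warning rather than an error.
#'
#' @param img Image array as returned by [load_image()].
#' @param cfg A [grain_config()].
#' @return Integer matrix of 0/1, same height/width as \code{img};
#'   1 marks grain pixels.
#' @export
binarize <- function(img, cfg = grain_config()) {
  g <- to_gray(img)
  if (diff(range(g)) < 1 / 255) {
    warning("uniform image: Otsu threshold is degenerate, returning empty mask")
    return(matrix(0L, nrow(g), ncol(g)))
  }
  k <- cfg$gaussian_kernel
  if (k > 1) {
    sigma <- effective_sigma(cfg)
    ax <- seq(-(k %/% 2), k %/% 2)
    k1 <- exp(-ax^2 / (2 * sigma^2))
    kern <- outer(k1, k1)
    kern <- kern / sum(kern)
    g <- EBImage::filter2(g, kern, boundary = "replicate")
    g <- pmin(pmax(g, 0), 1)
  }
  thr <- EBImage::otsu(EBImage::Image(g), range = c(0, 1), levels = 256)
  dark <- (g < thr)
  border <- c(dark[1, ], dark[nrow(dark), ], dark[, 1], dark[, ncol(dark)])
  fg <- if (mean(border) <= 0.5) dark else !dark
  if (!any(fg)) {
    warning("empty foreground after thresholding")
    return(matrix(0L, nrow(g), ncol(g)))
  }
  mask <- matrix(0L, nrow(g), ncol(g))
  mask[fg] <- 1L
  drop_small_components(mask, cfg$min_blob_area)
}

# remove 8-connected components below an area floor
drop_small_components <- function(mask, min_area) {
  if (min_area <= 1 || !any(mask == 1L)) return(mask)
  lab <- label_components(mask, 8L)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_area)
  if (length(small) > 0) {
    mask[lab %in% small] <- 0L
  }
  mask
}
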