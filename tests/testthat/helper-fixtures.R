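# Fixture builders and independent brute-force oracles used across tests.

# --- mask builders -----------------------------------------------------

disc_mask <- function(nr, nc, discs) {
  mm <- matrix(0L, nr, nc)
  ix <- as.matrix(expand.grid(1:nr, 1:nc))
  for (d in discs) {
    sel <- (ix[, 1] - d[1])^2 + (ix[, 2] - d[2])^2 <= d[3]^2
    mm[ix[sel, , drop = FALSE]] <- 1L
  }
  mm
}

ellipse_mask <- function(nr, nc, ells) {
  # ells: list of c(cr, cc, A, B, phi_degrees)
  mm <- matrix(0L, nr, nc)
  ix <- as.matrix(expand.grid(1:nr, 1:nc))
  for (e in ells) {
    phi <- e[5] * pi / 180
    dr <- ix[, 1] - e[1]; dc <- ix[, 2] - e[2]
    u <- dc * cos(phi) + dr * sin(phi)
    v <- -dc * sin(phi) + dr * cos(phi)
    sel <- (u / e[3])^2 + (v / e[4])^2 <= 1
    mm[ix[sel, , drop = FALSE]] <- 1L
  }
  mm
}

rect_mask <- function(nr, nc, r0, c0, h, w) {
  mm <- matrix(0L, nr, nc)
  mm[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1L
  mm
}

# grayscale image (dark shapes on white) from a mask, no noise
mask_to_image <- function(mask, fg = 70 / 255, bg = 245 / 255) {
  img <- matrix(bg, nrow(mask), ncol(mask))
  img[mask == 1L] <- fg
  img
}

# --- oracles (straight-line reimplementations, no shared code paths) ---

# window foreground fraction at (r, c): count pixels one by one; pixels
# beyond the matrix count as background, denominator is the full window
oracle_window_fraction <- function(mask, r, c, win) {
  rad <- win %/% 2
  s <- 0L
  for (dr in -rad:rad) for (dc in -rad:rad) {
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
        mask[rr, cc] == 1L) s <- s + 1L
  }
  s / (win * win)
}

# boundary pixels by definition: foreground with a 4-neighbour that is
# background or out of frame
oracle_boundary <- function(mask) {
  out <- NULL
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] != 1L) next
    nb <- c(
      if (r > 1) mask[r - 1, c] else 0L,
      if (r < nrow(mask)) mask[r + 1, c] else 0L,
      if (c > 1) mask[r, c - 1] else 0L,
      if (c < ncol(mask)) mask[r, c + 1] else 0L)
    if (any(nb == 0L)) out <- rbind(out, c(r, c))
  }
  out
}

# hole count by explicit flood fill from the outside (4-connected bg)
oracle_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  visited <- p == 1L
  queue <- list(c(1L, 1L))
  visited[1, 1] <- TRUE
  while (length(queue) > 0) {
    q <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- q[1] + d[1]; cc <- q[2] + d[2]
      if (rr >= 1 && rr <= nr + 2 && cc >= 1 && cc <= nc + 2 &&
          !visited[rr, cc]) {
        visited[rr, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
  }
  # remaining unvisited background = enclosed holes; count components
  holes <- 0L
  for (r in seq_len(nr + 2)) for (c in seq_len(nc + 2)) {
    if (visited[r, c]) next
    holes <- holes + 1L
    queue <- list(c(r, c))
    visited[r, c] <- TRUE
    while (length(queue) > 0) {
      q <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- q[1] + d[1]; cc <- q[2] + d[2]
        if (rr >= 1 && rr <= nr + 2 && cc >= 1 && cc <= nc + 2 &&
            !visited[rr, cc]) {
          visited[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  holes
}

# brute-force binary erosion by a Euclidean disk of the given radius
oracle_erode_disk <- function(mask, radius) {
  offs <- as.matrix(expand.grid(dr = -ceiling(radius):ceiling(radius),
                                dc = -ceiling(radius):ceiling(radius)))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= radius^2, , drop = FALSE]
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] != 1L) next
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    inside <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    if (all(inside) && all(mask[cbind(rr, cc)] == 1L)) out[r, c] <- 1L
  }
  out
}

n_components <- function(mask, conn = 8L) {
  max(graincountr:::label_components(mask, conn))
}

# --- JPEG with an EXIF orientation tag ---------------------------------

# wraps jpeg::writeJPEG output with a minimal APP1/EXIF segment carrying
# only the orientation entry
write_jpeg_with_orientation <- function(img, path, orientation) {
  plain <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(img, plain, quality = 0.95)
  bytes <- readBin(plain, "raw", n = file.size(plain))
  unlink(plain)
  u16 <- function(x) as.raw(c(x %/% 256, x %% 256))        # big endian
  u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  tiff <- c(
    charToRaw("II"), u16le(42), u32le(8),   # little-endian TIFF, IFD at 8
    u16le(1),                               # one IFD entry
    u16le(0x0112), u16le(3), u32le(1),      # orientation, SHORT, count 1
    u16le(orientation), u16le(0),           # value + padding
    u32le(0))                               # no next IFD
  payload <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  app1 <- c(as.raw(c(0xff, 0xe1)), u16(length(payload) + 2), payload)
  out <- c(bytes[1:2], app1, bytes[3:length(bytes)])
  writeBin(out, path)
  path
}
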