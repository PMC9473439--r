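# Region labelling, corners, the count formula, corrections, whole-image
# counting.

cfg <- grain_config()

test_that("label_regions reports components, holes and geometry", {
  m <- matrix(0L, 60, 120)
  m[10:19, 10:19] <- 1L; m[10:19, 40:49] <- 1L; m[40:49, 80:89] <- 1L
  regs <- label_regions(m, cfg)
  expect_equal(nrow(regs), 3)
  expect_equal(regs$holes, c(0L, 0L, 0L))
  expect_equal(regs$area, rep(100, 3))

  ring <- disc_mask(50, 50, list(c(25, 25, 15)))
  ring[disc_mask(50, 50, list(c(25, 25, 8))) == 1L] <- 0L
  rr <- label_regions(ring, cfg)
  expect_equal(nrow(rr), 1)
  expect_equal(rr$holes, 1L)

  sc <- generate_scene(50, "wheat", adhesion_frac = 0, seed = 7)
  expect_equal(nrow(label_regions(binarize(sc$image), cfg)), 50)
})

test_that("hole counting matches the flood-fill oracle", {
  solid <- ellipse_mask(60, 90, list(c(30, 45, 30, 12, 15)))
  expect_equal(count_holes(solid), 0L)
  expect_equal(count_holes(solid), oracle_holes(solid))

  # ring of 6 touching circles around a central gap
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring6 <- disc_mask(90, 90, lapply(ang, function(a)
    c(45 + 26 * sin(a), 45 + 26 * cos(a), 14)))
  expect_equal(n_components(ring6), 1)
  expect_equal(count_holes(ring6), 1L)
  expect_equal(count_holes(ring6), oracle_holes(ring6))

  # figure-eight: two rings sharing a neck
  r1 <- disc_mask(60, 100, list(c(30, 30, 16)))
  r1[disc_mask(60, 100, list(c(30, 30, 9))) == 1L] <- 0L
  r2 <- disc_mask(60, 100, list(c(30, 58, 16)))
  r2[disc_mask(60, 100, list(c(30, 58, 9))) == 1L] <- 0L
  eight <- pmax(r1, r2)
  expect_equal(n_components(eight), 1)
  expect_equal(count_holes(eight), 2L)
  expect_equal(count_holes(eight), oracle_holes(eight))
})

test_that("convex boundaries yield no corners; concave necks yield two", {
  circ <- disc_mask(100, 100, list(c(50, 50, 30)))
  regs <- label_regions(circ, cfg)
  expect_equal(nrow(detect_corners(regs[1, ], mask = circ, cfg = cfg)), 0)

  half <- matrix(0L, 60, 60); half[30:60, ] <- 1L
  hr <- label_regions(half, cfg)
  expect_equal(nrow(detect_corners(hr[1, ], mask = half, cfg = cfg)), 0)

  pair <- disc_mask(80, 110, list(c(40, 40, 15), c(40, 64, 15)))
  pr <- label_regions(pair, cfg)
  co <- detect_corners(pr[1, ], mask = pair, cfg = cfg)
  expect_equal(nrow(co), 2)
  # both corners sit at the concave neck (x near the midline 52)
  expect_true(all(abs(co$col - 52) <= 3))
  expect_true(all(co$score > cfg$corner_fraction))
})

test_that("corner detection agrees with the exhaustive fraction oracle", {
  fixtures <- list(
    disc_mask(90, 130, list(c(45, 45, 16), c(45, 72, 16))),
    ellipse_mask(100, 170, list(c(50, 60, 28, 12, 10), c(56, 105, 28, 12, -8))),
    disc_mask(80, 80, list(c(40, 40, 22))))
  for (m in fixtures) {
    regs <- label_regions(m, cfg)
    got <- detect_corners(regs[1, ], mask = m, cfg = cfg)
    # oracle: per-boundary-pixel fraction, then the same published
    # candidate + suppression rule, written independently
    bpx <- oracle_boundary(m)
    fr <- apply(bpx, 1, function(p)
      oracle_window_fraction(m, p[1], p[2], cfg$corner_window))
    cand <- which(fr > cfg$corner_fraction)
    keep <- integer(0)
    for (i in cand[order(-fr[cand], bpx[cand, 1], bpx[cand, 2])]) {
      if (length(keep) == 0 ||
          all(pmax(abs(bpx[keep, 1] - bpx[i, 1]),
                   abs(bpx[keep, 2] - bpx[i, 2])) > cfg$corner_window)) {
        keep <- c(keep, i)
      }
    }
    want <- bpx[keep, , drop = FALSE]
    got_m <- as.matrix(got[, c("row", "col")])
    norm <- function(m) {
      m <- matrix(as.numeric(m), ncol = 2)
      m[order(m[, 1], m[, 2]), , drop = FALSE]
    }
    expect_equal(norm(got_m), norm(want))
  }
})

test_that("the count formula is exact, linear in corners, unit per hole", {
  expect_identical(region_count_formula(0, 0), 1)
  expect_identical(region_count_formula(1, 0), 1.5)
  expect_identical(region_count_formula(12, 0), 7)
  expect_identical(region_count_formula(17, 0), 9.5)
  for (k in 0:40) for (h in 0:5) {
    expect_identical(region_count_formula(k, h), k / 2 - h + 1)
  }
  expect_error(region_count_formula(-1, 0))
  expect_error(region_count_formula(2, -1))
})

test_that("linear adhesions are recognised by length and straightness", {
  straight <- ellipse_mask(80, 190, list(c(40, 60, 30, 12, 0),
                                         c(40, 115, 30, 12, 0)))
  regs <- label_regions(straight, cfg)
  len <- regs$skeleton_length[1]
  expect_true(is_linear_adhesion(regs[1, ], len / 2.0, cfg))   # 2.0x mean
  expect_false(is_linear_adhesion(regs[1, ], len / 1.2, cfg))  # 1.2x mean

  # L-shaped region: long but bent far outside the 160-200 degree band
  ell <- matrix(0L, 120, 120)
  ell[50:61, 20:100] <- 1L
  ell[50:115, 20:31] <- 1L
  lr <- label_regions(ell, cfg)
  expect_false(is_linear_adhesion(lr[1, ], lr$skeleton_length[1] / 2.0, cfg))
})

test_that("average-area fallback rounds half up with a floor of one", {
  expect_identical(average_area_count(200, 100), 2L)
  expect_identical(average_area_count(100, 100), 1L)
  expect_identical(average_area_count(240, 100), 2L)
  expect_identical(average_area_count(250, 100), 3L)
  expect_identical(average_area_count(20, 100), 1L)
  expect_error(average_area_count(100, 0))
})

test_that("count_image counts singles, pairs and empty masks", {
  sc <- generate_scene(50, "mung", adhesion_frac = 0, seed = 21)
  res <- count_grains(sc$image, cfg)
  expect_s3_class(res, "grain_count")
  expect_equal(res$total, 50)
  expect_true(all(tidy(res)$method == "single"))
  expect_equal(res$total, sum(tidy(res)$corrected))

  pair <- disc_mask(80, 110, list(c(40, 40, 15), c(40, 64, 15)))
  rp <- suppressWarnings(count_image(pair, cfg))
  expect_equal(rp$total, 2)

  expect_warning(r0 <- count_image(matrix(0L, 40, 40), cfg), "empty")
  expect_equal(r0$total, 0L)
})

test_that("a long unsplittable adhesion is counted by average area", {
  # capsules (constant width): erosion cannot split them and no boundary
  # point is concave. One capsule is three times the singles' length, so
  # only the skeleton length/angle rule can catch it.
  capsule <- function(m, r0, c0, len, hw = 12) {
    m[pmax(disc_mask(nrow(m), ncol(m),
                     list(c(r0, c0, hw), c(r0, c0 + len, hw))),
           rect_mask(nrow(m), ncol(m), r0 - hw, c0, 2 * hw + 1, len + 1)) == 1L] <- 1L
    m
  }
  m <- matrix(0L, 260, 260)
  m <- capsule(m, 35, 60, 120)                      # the long adhesion
  m <- capsule(m, 95, 40, 30);  m <- capsule(m, 95, 140, 30)
  m <- capsule(m, 155, 40, 30); m <- capsule(m, 155, 140, 30)
  m <- capsule(m, 215, 90, 30)                      # five singles
  res <- count_image(m, cfg)
  t <- tidy(res)
  long <- t[which.max(t$area), ]
  expect_equal(long$method, "average_area")
  expect_equal(long$corrected, 3L)
  expect_equal(res$total, 8)
})

test_that("the image total is rotation invariant", {
  sc <- generate_scene(60, "soybean", adhesion_frac = 0.25, seed = 13,
                       canvas = c(800, 1000))
  mask <- binarize(sc$image)
  totals <- c(
    count_image(mask, cfg)$total,
    count_image(mask[nrow(mask):1, ][, ncol(mask):1], cfg)$total,     # 180
    count_image(t(mask)[ncol(mask):1, ], cfg)$total,                  # 90
    count_image(t(mask)[, nrow(mask):1], cfg)$total)                  # 270
  expect_lte(max(totals) - min(totals), ceiling(0.02 * sc$N1))
})

test_that("corners and holes are measured on pre-erosion geometry", {
  # ring of touching discs: erosion may fragment it, but the hole and the
  # junction corners belong to the original annulus-like union
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring6 <- disc_mask(90, 90, lapply(ang, function(a)
    c(45 + 26 * sin(a), 45 + 26 * cos(a), 14)))
  res <- suppressWarnings(count_image(ring6, cfg))
  expect_equal(res$total, 6)
})
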