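# Skeletons, short-axis estimation, adaptive erosion.

test_that("skeleton of a bar is a single path of about its length", {
  m <- matrix(0L, 30, 60); m[12:19, 11:50] <- 1L   # 40x8 bar
  sk <- skeletonize(m)[[1]]
  expect_gte(sk$total_length, 30)
  expect_lte(sk$total_length, 40)
  expect_equal(nrow(sk$endpoints), 2)
  expect_equal(nrow(sk$branch_points), 0)
})

test_that("degenerate regions skeletonize without error", {
  m <- matrix(0L, 10, 10); m[5, 5] <- 1L
  sk <- skeletonize(m)[[1]]
  expect_equal(sk$pixels, cbind(5L, 5L))
  expect_equal(sk$total_length, 0)
  expect_equal(skeletonize(matrix(0L, 5, 5)), list())
})

test_that("thinning preserves topology: components and holes survive", {
  ring <- disc_mask(50, 50, list(c(25, 25, 18)))
  ring[disc_mask(50, 50, list(c(25, 25, 10))) == 1L] <- 0L
  thin <- graincountr:::thin_mask(ring)
  expect_equal(n_components(thin), 1)
  expect_equal(oracle_holes(thin), 1)   # cycle survives

  three <- disc_mask(60, 160, list(c(30, 30, 10), c(30, 80, 10), c(30, 130, 10)))
  expect_equal(n_components(graincountr:::thin_mask(three)), 3)
})

test_that("two collinear touching ellipses give one long skeleton", {
  m <- ellipse_mask(80, 190, list(c(40, 60, 30, 12, 0), c(40, 118, 30, 12, 0)))
  expect_equal(n_components(m), 1)
  sk <- skeletonize(m)[[1]]
  expect_equal(sk$total_length, 120, tolerance = 0.15)  # sum of major axes
})

test_that("short axis matches known widths", {
  cm <- disc_mask(80, 80, list(c(40, 40, 15)))
  skc <- skeletonize(cm)[[1]]
  expect_equal(estimate_short_axis(cm, skc)$X, 30, tolerance = 1 / 30)

  el <- ellipse_mask(80, 120, list(c(40, 60, 30, 12, 0)))
  ske <- skeletonize(el)[[1]]
  expect_equal(estimate_short_axis(el, ske)$X, 24, tolerance = 2 / 24)

  # two overlapped identical ellipses: width at the medial line, not the
  # union bounding box
  ov <- ellipse_mask(90, 170, list(c(42, 60, 30, 12, 0), c(44, 100, 30, 12, 0)))
  expect_equal(n_components(ov), 1)
  sko <- skeletonize(ov)[[1]]
  expect_equal(estimate_short_axis(ov, sko)$X, 24, tolerance = 3.5 / 24)
})

test_that("short axis is rotation-robust", {
  xs <- vapply(seq(0, 170, by = 10), function(a) {
    m <- ellipse_mask(120, 120, list(c(60, 60, 30, 12, a)))
    estimate_short_axis(m, skeletonize(m)[[1]])$X
  }, numeric(1))
  expect_lte((max(xs) - min(xs)) / mean(xs), 0.10)
})

test_that("erosion extent follows e = w * X with a 1 px floor", {
  expect_identical(erosion_extent(20, 0.4), 8L)
  expect_identical(erosion_extent(1, 0.4), 1L)
  expect_identical(erosion_extent(25, 0.8), 20L)
  expect_error(erosion_extent(0, 0.4))
  expect_error(erosion_extent(10, 1.2))
})

test_that("separate matches brute-force disk erosion on a clean pair", {
  # shallow 1 px overlap: neck (3.4 px) is thinner than the erosion radius
  m <- disc_mask(70, 100, list(c(35, 40, 12), c(35, 63, 12)))
  expect_equal(n_components(m), 1)
  X <- 2 * max(graincountr:::distmap_bg(m))
  e <- erosion_extent(X, 0.4)
  oracle <- oracle_erode_disk(m, e)
  expect_equal(n_components(oracle), 2)
  sep <- separate(m, grain_config())
  expect_equal(n_components(sep), 2)
  # eroded pixels are a subset of the oracle's surviving set's region
  expect_true(all(m[sep == 1L] == 1L))
})

test_that("separation never deletes a grain and never merges regions", {
  single <- ellipse_mask(80, 120, list(c(40, 60, 30, 12, 20)))
  sep <- separate(single, grain_config())
  expect_equal(n_components(sep), 1)

  sc <- generate_scene(30, "wheat", adhesion_frac = 0.4, seed = 9,
                       canvas = c(600, 800))
  mask <- binarize(sc$image)
  before <- n_components(mask)
  sep2 <- separate(mask, grain_config())
  expect_gte(n_components(sep2), before)
  expect_lte(sum(sep2), sum(mask))
  # vanish guard: every region keeps at least one pixel
  lab <- graincountr:::label_components(mask, 8L)
  surviving <- unique(lab[sep2 == 1L])
  expect_setequal(surviving, seq_len(before))
})

test_that("a tangential chain of round grains separates into its grains", {
  r <- 12
  centers <- lapply(0:4, function(k) c(40, 25 + k * (2 * r - 1), r))
  m <- disc_mask(80, 160, centers)
  expect_equal(n_components(m), 1)
  sep <- separate(m, grain_config())
  expect_equal(n_components(sep), 5)
})
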