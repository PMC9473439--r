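# Annotation arithmetic, rendering, tidiers, structured output, CLI.

test_that("annotation totals follow the red-dot / yellow-number rule", {
  ann <- tibble::tibble(row = c(10, 20, 30, 40), col = c(10, 20, 30, 40),
                        count = c(1L, 1L, 3L, 2L),
                        labeled = c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(total_from_annotation(ann), 7L)   # 2 dots + 3 + 2

  plain <- tibble::tibble(row = 1:5, col = 1:5, count = rep(1L, 5),
                          labeled = rep(FALSE, 5))
  expect_identical(total_from_annotation(plain), 5L)

  one <- tibble::tibble(row = 1, col = 1, count = 4L, labeled = TRUE)
  expect_identical(total_from_annotation(one), 4L)

  # the list form mirrors the drawn artefacts
  lst <- list(dots = cbind(c(10, 20, 30), c(10, 20, 30)),
              adhesion_labels = list(list(position = c(30, 30), count = 3)))
  expect_identical(total_from_annotation(lst), 5L)
})

test_that("every count result round-trips through its annotation", {
  sc <- generate_scene(25, "wheat", adhesion_frac = 0.3, seed = 33,
                       canvas = c(600, 800))
  res <- count_grains(sc$image)
  expect_identical(total_from_annotation(res$annotations), res$total)
})

test_that("annotate_image draws dots and labels without touching the input", {
  sc <- generate_scene(6, "soybean", adhesion_frac = 0.4, seed = 19,
                       canvas = c(400, 500))
  res <- count_grains(sc$image)
  img <- attr(res, "image")
  before <- img
  out <- annotate_image(img, res)
  expect_identical(img, before)
  expect_equal(dim(out), c(dim(img), 3))
  # red dots present at centroids
  i <- round(res$annotations$row[1]); j <- round(res$annotations$col[1])
  expect_equal(out[i, j, ], c(1, 0, 0))

  oob <- res
  oob$annotations$row[1] <- -5
  expect_warning(annotate_image(img, oob), "outside image")
})

test_that("tidy, glance and autoplot expose the result", {
  sc <- generate_scene(10, "mung", seed = 3, canvas = c(400, 500))
  res <- count_grains(sc$image)
  t <- tidy(res)
  expect_s3_class(t, "tbl_df")
  expect_equal(sum(t$corrected), res$total)
  g <- glance(res)
  expect_equal(g$total, res$total)
  expect_equal(g$n_units, nrow(t))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("JSON and CSV outputs agree on every per-region count", {
  sc <- generate_scene(15, "peanut", adhesion_frac = 0.2, seed = 27,
                       canvas = c(500, 700))
  res <- count_grains(sc$image)
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_result_json(res, pj, truth = sc$N1)
  write_result_csv(res, pc)
  j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  csv <- utils::read.csv(pc)
  expect_equal(j$total, res$total)
  expect_equal(j$regions$corrected, csv$corrected)
  expect_equal(j$truth, sc$N1)
  expect_equal(j$CR + j$ER, 100)
})

test_that("the CLI counts, synthesises and fails with proper codes", {
  td <- withr::local_tempdir()
  scene_png <- file.path(td, "scene.png")
  expect_identical(cli_main(c("synth", "--n", "20", "--preset", "mung",
                              "--seed", "5", "--out", scene_png)), 0L)
  scene2 <- file.path(td, "scene2.png")
  expect_identical(cli_main(c("synth", "--n", "20", "--preset", "mung",
                              "--seed", "5", "--out", scene2)), 0L)
  expect_identical(readBin(scene_png, "raw", file.size(scene_png)),
                   readBin(scene2, "raw", file.size(scene2)))

  out_json <- file.path(td, "out.json")
  out_csv <- file.path(td, "out.csv")
  ann_png <- file.path(td, "ann.png")
  code <- suppressMessages(
    cli_main(c("count", scene_png, "--json", out_json, "--csv", out_csv,
               "--annotate", ann_png, "--truth", "20")))
  expect_identical(code, 0L)
  j <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_equal(j$total, 20)
  expect_true(file.exists(out_csv))
  expect_true(file.exists(ann_png))

  expect_identical(suppressMessages(
    cli_main(c("count", file.path(td, "missing.png")))), 1L)
  expect_identical(suppressMessages(
    cli_main(c("count", scene_png, "--bogus", "x"))), 2L)
  expect_identical(suppressMessages(cli_main(character(0))), 2L)
})
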