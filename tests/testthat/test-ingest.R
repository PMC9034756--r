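make_test_tiff <- function(path, shape = c(40, 56), channels = 1,
                           bits = 16L, seed = 5) {
  withr::with_seed(seed, {
    mx <- 2^bits - 1
    if (channels == 1) {
      img <- matrix(sample.int(mx + 1, prod(shape), replace = TRUE) - 1,
                    shape[1], shape[2])
      tiff::writeTIFF(img / mx, path, bits.per.sample = bits)
      img
    } else {
      pages <- lapply(seq_len(channels), function(k)
        matrix(sample.int(mx + 1, prod(shape), replace = TRUE) - 1,
               shape[1], shape[2]))
      tiff::writeTIFF(lapply(pages, function(p) p / mx), path,
                      bits.per.sample = bits)
      pages
    }
  })
}

test_that("read_slice_image loads single- and multi-channel TIFFs", {
  d <- withr::local_tempdir()
  f3 <- file.path(d, "tri.tif")
  pages <- make_test_tiff(f3, channels = 3)
  rs <- read_slice_image(f3, 0.5, c("dapi", "gfp", "mcherry"))
  expect_identical(dim(rs$image), c(40L, 56L, 3L))
  expect_identical(rs$image[, , 2], matrix(as.integer(pages[[2]]), 40, 56))
  expect_identical(rs$channel_names, c("dapi", "gfp", "mcherry"))

  f1 <- file.path(d, "mono.tif")
  img <- make_test_tiff(f1, bits = 8L)
  rs1 <- read_slice_image(f1, 1)
  expect_identical(dim(rs1$image), c(40L, 56L, 1L))
  expect_identical(rs1$image[, , 1], matrix(as.integer(img), 40, 56))

  expect_error(read_slice_image(file.path(d, "img.png"), 0.5),
               "tif", class = "histoslice_format_error")
  expect_error(read_slice_image(f3, 0.5, c("a", "b")), "3 channels")
})

test_that("read_points parses FIJI CSVs preserving order and multiplicity", {
  d <- withr::local_tempdir()
  f <- file.path(d, "cells.csv")
  readr::write_csv(tibble::tibble(
    ` ` = 1:5, Area = runif(5), X = c(10.5, 3, 200, 3, 7.25),
    Y = c(4, 90, 33.3, 90, 0)), f)
  ps <- read_points(f, "fiji_csv")
  expect_s3_class(ps, "point_set")
  expect_equal(nrow(ps), 5)
  expect_equal(ps$x, c(10.5, 3, 200, 3, 7.25))
  expect_equal(point_frame(ps), "raw")
  expect_identical(attr(ps, "source_image"), "cells")
  # duplicates rows 2 and 4 both kept
  expect_equal(sum(ps$x == 3 & ps$y == 90), 2)

  empty <- file.path(d, "none.csv")
  file.create(empty)
  expect_equal(nrow(read_points(empty, "fiji_csv")), 0)

  bad <- file.path(d, "bad.csv")
  readr::write_csv(tibble::tibble(A = 1:2, B = 3:4), bad)
  expect_error(read_points(bad, "fiji_csv"), "X")
})

test_that("photoshop count-tool text exports convert to the same points", {
  d <- withr::local_tempdir()
  f <- file.path(d, "counts.txt")
  writeLines(c("Number\tX\tY", "1\t100.5\t30", "2\t7\t8.25"), f)
  ps <- read_points(f, "photoshop_txt")
  expect_equal(ps$x, c(100.5, 7))
  expect_equal(ps$y, c(30, 8.25))
})

test_that("calibrated FIJI exports convert microns back to pixels", {
  d <- withr::local_tempdir()
  f <- file.path(d, "cal.csv")
  readr::write_csv(tibble::tibble(X = c(5, 10), Y = c(2.5, 0)), f)
  ps <- read_points(f, "fiji_csv", calibrated_um = 0.5)
  expect_equal(ps$x, c(10, 20))
  expect_equal(ps$y, c(5, 0))
})

test_that("preprocess downsamples, centres and maps points consistently", {
  d <- withr::local_tempdir()
  f <- file.path(d, "s.tif")
  make_test_tiff(f, shape = c(400, 560))
  rs <- read_slice_image(f, 0.5)  # 0.5 um/px -> f = 1/20 at 10 um
  ps <- point_set(c(100, 0, 399.5), c(40, 0, 200), frame = "raw",
                  source_image = "s")
  pp <- preprocess(rs, ps, atlas_voxel_um = 10, canvas = c(80, 114))
  expect_identical(dim(pp$image)[1:2], c(80L, 114L))
  # 400x560 -> 20x28, centred: offsets (30, 43)
  expect_equal(pp$canvas_record$pad_offset, c(30, 43))
  expect_equal(pp$canvas_record$scale_factor, 20)
  expect_equal(pp$points$x, c(100, 0, 399.5) / 20 + 43)
  expect_equal(pp$points$y, c(40, 0, 200) / 20 + 30)
  expect_equal(point_frame(pp$points), "padded")
  # content is conserved: area-average preserves the mean over the block
  inner <- pp$image[30 + 1:20, 43 + 1:28, 1]
  expect_equal(mean(inner), mean(rs$image), tolerance = 1e-12)
  expect_equal(inner[1, 1], mean(rs$image[1:20, 1:20, 1]), tolerance = 1e-12)

  # inverse mapping recovers raw coordinates
  back <- unpad_points(pp$points, pp$canvas_record)
  expect_equal(back$x, ps$x, tolerance = 1e-9)
  expect_equal(back$y, ps$y, tolerance = 1e-9)
})

test_that("an image already at atlas resolution and canvas size passes through", {
  d <- withr::local_tempdir()
  f <- file.path(d, "id.tif")
  img <- make_test_tiff(f, shape = c(80, 114))
  rs <- read_slice_image(f, 10)
  pp <- preprocess(rs, NULL, atlas_voxel_um = 10, canvas = c(80, 114))
  expect_equal(pp$canvas_record$pad_offset, c(0, 0))
  expect_equal(pp$image[, , 1], matrix(as.numeric(img), 80, 114))
})

test_that("preprocess rejects oversized input and mismatched pairing", {
  d <- withr::local_tempdir()
  f <- file.path(d, "big.tif")
  make_test_tiff(f, shape = c(60, 60))
  rs <- read_slice_image(f, 10)
  expect_error(preprocess(rs, NULL, canvas = c(40, 40)), "canvas")
  ps <- point_set(1, 1, frame = "raw", source_image = "other")
  expect_error(preprocess(rs, ps, canvas = c(80, 114)),
               class = "histoslice_pairing_error")
  expect_error(preprocess(read_slice_image(f, 10), NULL, atlas_voxel_um = 5),
               "exceed")
})

test_that("contrast adjustment rescales intensities but nothing else", {
  d <- withr::local_tempdir()
  f <- file.path(d, "c.tif")
  make_test_tiff(f, shape = c(40, 40))
  rs <- read_slice_image(f, 10)
  ps <- point_set(c(3, 17), c(5, 20), frame = "raw", source_image = "c")
  plain <- preprocess(rs, ps, canvas = c(40, 40))
  stretched <- preprocess(rs, ps, canvas = c(40, 40),
                          contrast = list(low = 0.1, high = 0.9))
  expect_identical(dim(stretched$image), dim(plain$image))
  expect_identical(stretched$points$x, plain$points$x)
  expect_identical(stretched$points$y, plain$points$y)
  expect_gt(stats::sd(stretched$image), stats::sd(plain$image) * 1.01)
})

test_that("points_to_mask rasterizes with half-up rounding", {
  ps <- point_set(c(10.4, 3, 3), c(20.7, 8, 8), frame = "raw")
  m <- points_to_mask(ps, c(30, 30))
  expect_equal(sum(m), 2)  # two points share a pixel: multiplicity collapses
  expect_true(m[22, 11])   # (y 20.7 -> row 21, x 10.4 -> col 10), 0-based
  expect_true(m[9, 4])
  expect_equal(sum(points_to_mask(point_set(frame = "raw"), c(5, 5))), 0)
  expect_error(points_to_mask(point_set(29.8, 1, frame = "raw"), c(30, 30)),
               "outside")
})

test_that("mask pixel count equals point count when no pixels collide", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      pts <- expand.grid(x = seq(2, 60, by = 4), y = seq(2, 60, by = 4))
      pick <- sample.int(nrow(pts), 30)
      ps <- point_set(pts$x[pick] + runif(30, -0.4, 0.4),
                      pts$y[pick] + runif(30, -0.4, 0.4), frame = "raw")
      expect_equal(sum(points_to_mask(ps, c(70, 70))), nrow(ps))
    }
  })
})
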