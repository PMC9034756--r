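gen_landmarks <- function(n = 10, seed = 3, H = NULL, sigma = 0) {
  withr::with_seed(seed, {
    src <- cbind(runif(n, 5, 95), runif(n, 5, 75))
    dst <- if (is.null(H)) src else {
      w <- H[3, 1] * src[, 1] + H[3, 2] * src[, 2] + H[3, 3]
      cbind((H[1, 1] * src[, 1] + H[1, 2] * src[, 2] + H[1, 3]) / w,
            (H[2, 1] * src[, 1] + H[2, 2] * src[, 2] + H[2, 3]) / w)
    }
    if (sigma > 0) src <- src + rnorm(2 * n, 0, sigma)
    landmark_set(src, dst)
  })
}

test_that("identity landmarks give an identity transform with zero residuals", {
  lms <- gen_landmarks(10)
  for (family in c("affine", "projective", "thin_plate_spline")) {
    tf <- fit_transform(lms, family)
    expect_equal(max(tf$fit_residuals), 0, tolerance = 1e-8, info = family)
    ps <- point_set(c(10, 50.5, 80), c(12, 33, 60), frame = "padded")
    out <- warp_points(ps, tf)
    expect_equal(out$x, ps$x, tolerance = 1e-7)
    expect_equal(out$y, ps$y, tolerance = 1e-7)
  }
})

test_that("known affine and projective transforms are recovered to 1e-6", {
  A <- matrix(c(1.1, 0.2, 5, -0.15, 0.9, -3, 0, 0, 1), 3, 3, byrow = TRUE)
  tfa <- fit_transform(gen_landmarks(6, H = A), "affine", strict = FALSE)
  expect_equal(matrix(unlist(tfa$params), 3, 3), A, tolerance = 1e-6)

  H <- demo_homography()
  tfp <- fit_transform(gen_landmarks(12, H = H), "projective")
  expect_equal(matrix(unlist(tfp$params), 3, 3) /
                 matrix(unlist(tfp$params), 3, 3)[3, 3],
               H / H[3, 3], tolerance = 1e-6)
  expect_lt(max(tfp$fit_residuals), 1e-6)
})

test_that("under-determined and degenerate configurations are rejected", {
  expect_error(fit_transform(gen_landmarks(3), "projective", strict = FALSE),
               "under-determined", class = "histoslice_underdetermined")
  expect_error(fit_transform(gen_landmarks(2), "affine", strict = FALSE),
               class = "histoslice_underdetermined")
  collinear <- landmark_set(cbind(1:6, 2 * (1:6)), cbind(1:6, 2 * (1:6)))
  expect_error(fit_transform(collinear, "affine", strict = FALSE),
               class = "histoslice_degenerate")
  expect_error(landmark_set(cbind(c(1, 1), c(2, 2)), cbind(c(1, 2), c(2, 3))),
               "duplicated")
})

test_that("strict mode enforces the 10-landmark recommendation by default", {
  lms9 <- gen_landmarks(9)
  expect_error(fit_transform(lms9), "10",
               class = "histoslice_strict_landmarks")
  expect_s3_class(fit_transform(lms9, strict = FALSE), "planar_transform")
  expect_s3_class(fit_transform(gen_landmarks(10)), "planar_transform")
})

test_that("thin-plate spline interpolates landmarks exactly", {
  withr::with_seed(9, {
    src <- cbind(runif(12, 0, 100), runif(12, 0, 80))
    dst <- src + cbind(rnorm(12, 0, 4), rnorm(12, 0, 4))  # local warps
  })
  tf <- fit_transform(landmark_set(src, dst), "thin_plate_spline")
  expect_equal(max(tf$fit_residuals), 0, tolerance = 1e-7)
})

test_that("warp_points matches an independent homogeneous-coordinates oracle", {
  H <- demo_homography()
  tf <- fit_transform(gen_landmarks(12, H = H), "projective")
  withr::with_seed(4, {
    ps <- point_set(runif(100, 0, 100), runif(100, 0, 80), frame = "padded")
  })
  out <- warp_points(ps, tf)
  M <- H %*% rbind(ps$x, ps$y, 1)
  expect_equal(out$x, M[1, ] / M[3, ], tolerance = 1e-9)
  expect_equal(out$y, M[2, ] / M[3, ], tolerance = 1e-9)
  expect_equal(nrow(out), 100)
  expect_equal(point_frame(out), "atlas")
})

test_that("warp_points preserves count, order and extra columns", {
  tf <- matrix_transform(diag(3))
  ps <- point_set(c(5, 5, 9), c(1, 1, 2), label = c("a", "a", "b"),
                  frame = "padded")
  out <- warp_points(ps, tf)
  expect_identical(out$label, c("a", "a", "b"))
  expect_equal(nrow(out), 3)
  empty <- warp_points(point_set(frame = "padded"), tf)
  expect_equal(nrow(empty), 0)
})

test_that("warp_image honours identity, translation and projective mappings", {
  img <- matrix(0, 40, 50)
  img[20, 25] <- 100
  idt <- matrix_transform(diag(3))
  expect_equal(warp_image(img, idt, c(40, 50)), img)

  tr <- matrix_transform(matrix(c(1, 0, 5, 0, 1, 3, 0, 0, 1), 3, 3,
                                byrow = TRUE))
  moved <- warp_image(img, tr, c(40, 50))
  # impulse at (x=24, y=19) 0-based moves to (29, 22)
  expect_equal(moved[23, 30], 100)
  expect_equal(sum(moved), 100)

  # grid pattern under a real homography: peaks land within 0.5 px of the
  # per-point matrix mapping
  grid <- matrix(0, 60, 70)
  pts <- expand.grid(r = seq(10, 50, 10), c = seq(10, 60, 10))
  grid[as.matrix(pts)] <- 255
  H <- demo_homography()
  tf <- fit_transform(gen_landmarks(12, H = H), "projective")
  warped <- warp_image(grid, tf, c(60, 70))
  M <- H %*% rbind(pts$c - 1, pts$r - 1, 1)
  ex <- M[1, ] / M[3, ]; ey <- M[2, ] / M[3, ]
  for (i in seq_len(nrow(pts))) {
    win <- warped[pmax(1, round(ey[i]) - 1):pmin(60, round(ey[i]) + 3),
                  pmax(1, round(ex[i]) - 1):pmin(70, round(ex[i]) + 3)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    pr <- pmax(1, round(ey[i]) - 1) + peak[1] - 1
    pc <- pmax(1, round(ex[i]) - 1) + peak[2] - 1
    expect_lt(abs(pr - 1 - ey[i]), 1)
    expect_lt(abs(pc - 1 - ex[i]), 1)
  }
})

test_that("a warped impulse lands on the warped point (image/point consistency)", {
  H <- demo_homography()
  tf <- fit_transform(gen_landmarks(12, H = H), "projective")
  cell <- c(x = 40, y = 25)
  img <- matrix(0, 80, 100)
  img[cell["y"] + 1, cell["x"] + 1] <- 1000
  warped_img <- warp_image(img, tf, c(80, 100))
  wp <- warp_points(point_set(cell["x"], cell["y"], frame = "padded"), tf)
  peak <- which(warped_img == max(warped_img), arr.ind = TRUE)[1, ]
  expect_lt(abs((peak[1] - 1) - wp$y), 1)
  expect_lt(abs((peak[2] - 1) - wp$x), 1)
})

test_that("mean fit residual grows monotonically with landmark noise", {
  H <- demo_homography()
  res <- vapply(c(0, 0.5, 1, 2), function(s) {
    tf <- fit_transform(gen_landmarks(12, seed = 21, H = H, sigma = s),
                        "projective")
    mean(tf$fit_residuals)
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("transforms survive a save/load round trip bit-exactly", {
  d <- withr::local_tempdir()
  probe <- expand.grid(x = seq(0, 100, 12.5), y = seq(0, 80, 11))
  for (family in c("affine", "projective", "thin_plate_spline")) {
    tf <- fit_transform(gen_landmarks(10, H = demo_homography()), family,
                        sp = slice_plane("coronal", 1.35, -1.7, 3.6))
    f <- file.path(d, paste0(family, ".json"))
    save_transform(tf, f)
    tf2 <- load_transform(f)
    a <- histoslice:::transform_xy(tf, probe$x, probe$y)
    b <- histoslice:::transform_xy(tf2, probe$x, probe$y)
    expect_identical(a$x, b$x, info = family)
    expect_identical(a$y, b$y, info = family)
    expect_equal(tf2$slice_plane$position_mm, 1.35)
  }
})

test_that("apply_saved_transform equals in-memory warp_points", {
  d <- withr::local_tempdir()
  tf <- fit_transform(gen_landmarks(11, H = demo_homography()))
  f <- file.path(d, "t.json")
  save_transform(tf, f)
  ps <- point_set(c(1, 30, 70.5), c(2, 40, 40), frame = "padded")
  expect_identical(apply_saved_transform(f, ps), warp_points(ps, tf))
})

test_that("corrupted or wrong-version transform files are rejected", {
  d <- withr::local_tempdir()
  f <- file.path(d, "t.json")
  tf <- fit_transform(gen_landmarks(10))
  save_transform(tf, f)
  txt <- readLines(f, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), f)
  expect_error(load_transform(f), class = "histoslice_corrupt_file")
  jsonlite::write_json(list(schema_version = "9.9", family = "affine",
                            params = list(matrix = as.numeric(diag(3)))),
                       f, auto_unbox = TRUE)
  expect_error(load_transform(f), class = "histoslice_version_mismatch")
})

test_that("tidy and glance summarise fitted transforms", {
  tf <- fit_transform(gen_landmarks(10, H = demo_homography()))
  td <- tidy(tf)
  expect_equal(nrow(td), 9)
  expect_equal(td$estimate[td$term == "h33"], 1)
  gl <- glance(tf)
  expect_equal(gl$n_landmarks, 10)
  expect_lt(gl$rmse, 1e-6)
})
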