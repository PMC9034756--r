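test_that("assign_regions recovers the fixture's ground truth exactly", {
  fx <- toy_fixture()
  b <- fx$bundle
  rec <- assign_regions(fx$cell_points_atlas, b, fx$slice_plane, slice_id = "s1")
  expect_equal(nrow(rec$points), 50)
  expect_identical(rec$assignments$id, fx$true_assignments$id)
  expect_identical(rec$assignments$name, fx$true_assignments$name)
})

test_that("points off the canvas or outside the brain become outside-brain", {
  b <- toy_bundle()
  sp <- slice_plane("coronal", 0)
  ps <- point_set(c(0, -5, 2000, 50), c(0, 2, 3, 40), frame = "atlas")
  rec <- assign_regions(ps, b, sp)
  expect_equal(rec$assignments$name[1], "outside brain")  # background corner
  expect_equal(rec$assignments$name[2], "outside brain")  # off canvas
  expect_equal(rec$assignments$name[3], "outside brain")  # off canvas
  expect_equal(rec$assignments$id[4], 4L)                 # centre
  expect_equal(sum(tally_regions(rec)$count), 4)
})

test_that("sagittal quantification under the Chon labels is refused", {
  chon <- toy_bundle("chon")
  ps <- point_set(10, 10, frame = "atlas")
  expect_error(assign_regions(ps, chon, slice_plane("sagittal", 0)),
               class = "histoslice_chon_sagittal")
  # coronal under chon is fine
  rec <- assign_regions(ps, chon, slice_plane("coronal", 0))
  expect_s3_class(rec, "slice_record")
  # and sagittal under allen is fine
  rec2 <- assign_regions(ps, toy_bundle(), slice_plane("sagittal", 0))
  expect_s3_class(rec2, "slice_record")
})

test_that("assign_regions requires atlas-frame points", {
  b <- toy_bundle()
  ps <- point_set(1, 1, frame = "raw")
  expect_error(assign_regions(ps, b, slice_plane("coronal", 0)),
               class = "histoslice_frame_error")
})

test_that("assignment agrees with a brute-force per-point geometric chain", {
  H <- demo_homography()
  f <- 1 / 20
  pad <- c(7, 11)
  for (seed in 1:5) {
    b <- toy_bundle(seed = seed)
    sp <- slice_plane("coronal", 0.02 * seed, dv_tilt_deg = seed - 3,
                      ml_tilt_deg = 2 - seed)
    withr::with_seed(100 + seed, {
      n <- 200
      raw <- tibble::tibble(x = runif(n, 0, 1900), y = runif(n, 0, 1500))
    })
    padded <- point_set(raw$x * f + pad[2], raw$y * f + pad[1],
                        frame = "padded")
    atlas_pts <- warp_points(padded, matrix_transform(H))
    rec <- assign_regions(atlas_pts, b, sp)
    want <- vapply(seq_len(n), function(i)
      brute_force_assign(raw$x[i], raw$y[i], f, pad, H, b, sp), integer(1))
    expect_identical(rec$assignments$id, want)
  }
})

test_that("edit operations apply in order and log provenance", {
  ps <- point_set(c(1, 2, 3, 4), c(1, 2, 3, 4), frame = "atlas")
  out <- edit_points(ps, list(edit_delete(2),
                              edit_add(10, 11),
                              edit_move(1, 5, 6)))
  expect_equal(out$x, c(5, 3, 4, 10))
  expect_equal(out$y, c(6, 3, 4, 11))
  log <- attr(out, "edit_log")
  expect_equal(log$op, c("delete", "add", "move"))
  expect_error(edit_points(ps, edit_delete(9)), "out of range")
})

test_that("polygon group edits agree with a per-point membership oracle", {
  withr::with_seed(31, {
    ps <- point_set(runif(10, 0, 10), runif(10, 0, 10), frame = "atlas")
  })
  # triangle covering the lower-left corner
  tri <- rbind(c(0, 0), c(10, 0), c(0, 10))
  oracle_in <- vapply(seq_len(nrow(ps)), function(i) {
    # even-odd by explicit half-plane test for this triangle: x + y < 10
    ps$x[i] + ps$y[i] <= 10
  }, logical(1))
  out <- edit_points(ps, edit_polygon(tri, "delete"))
  expect_equal(nrow(out), sum(!oracle_in))
  expect_equal(out$x, ps$x[!oracle_in])

  shifted <- edit_points(ps, edit_polygon(tri, "translate", dx = 2, dy = -1))
  expect_equal(shifted$x, ps$x + ifelse(oracle_in, 2, 0))
  expect_equal(shifted$y, ps$y + ifelse(oracle_in, -1, 0))

  bow <- rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4))
  expect_error(edit_polygon(bow), class = "histoslice_polygon")
})

test_that("editing a slice record recomputes assignments", {
  b <- toy_bundle()
  sp <- slice_plane("coronal", 0)
  slc <- extract_slice(b, sp)
  ctr <- round((dim(b$annotation)[2:3] - 1) / 2)
  # a point in the innermost region, moved to a background corner
  rec <- assign_regions(point_set(ctr[2], ctr[1], frame = "atlas"), b, sp)
  expect_equal(rec$assignments$id, 4L)
  rec2 <- edit_points(rec, edit_move(1, 0, 0), bundle = b)
  expect_equal(rec2$assignments$name, "outside brain")
  expect_error(edit_points(rec, edit_move(1, 0, 0)), "bundle")
})

test_that("tally_regions is additive across slices and conserves totals", {
  fx <- toy_fixture()
  b <- fx$bundle
  sp <- fx$slice_plane
  rec1 <- assign_regions(fx$cell_points_atlas, b, sp, slice_id = "a")
  ctr <- round((dim(b$annotation)[2:3] - 1) / 2)
  rec2 <- assign_regions(point_set(c(ctr[2], ctr[2], 0), c(ctr[1], ctr[1], 0),
                                   frame = "atlas"), b, sp, slice_id = "b")
  brain <- tally_regions(list(rec1, rec2), "per_brain")
  expect_equal(attr(brain, "total"), 53)
  expect_equal(sum(brain$count), 53)
  expect_equal(brain$count[brain$id == 4] ,
               10 + 2)  # fixture midbrain cells + two centre points
  expect_equal(brain$count[brain$id == 0], 1)
  per_slice <- tally_regions(list(rec1, rec2), "per_slice")
  expect_equal(sum(per_slice$count), 53)
  sums <- tapply(per_slice$count, per_slice$slice_id, sum)
  expect_equal(as.vector(sums[c("a", "b")]), c(50, 3))
  # element-wise: per-brain equals the summed per-slice tables
  merged <- stats::aggregate(count ~ id, data = as.data.frame(per_slice), sum)
  expect_equal(brain$count[order(brain$id)], merged$count[order(merged$id)])

  expect_error(tally_regions(list(
    rec1, assign_regions(point_set(10, 10, frame = "atlas"),
                         toy_bundle("chon"), sp))),
    class = "histoslice_mixed_variants")

  empty <- tally_regions(list(), "per_brain")
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "total"), 0)
})

test_that("rollup accumulates leaf counts into ancestors", {
  fx <- toy_fixture()
  rec <- assign_regions(fx$cell_points_atlas, fx$bundle, fx$slice_plane)
  tab <- tally_regions(rec, "per_brain", rollup = TRUE,
                       tree = fx$bundle$structure_tree)
  expect_equal(tab$count[tab$id == 900], 50)  # root collects everything
  leaf <- tally_regions(rec, "per_brain")
  expect_equal(sum(leaf$count), 50)
})

test_that("to_ccf3d converts sampled voxels to microns consistently", {
  b <- toy_bundle()
  sp <- slice_plane("coronal", index_to_mm(b, 20, "coronal"))
  ps <- point_set(c(50, 0), c(40, 0), frame = "atlas")
  rec <- assign_regions(ps, b, sp)
  cloud <- to_ccf3d(rec, b)
  expect_equal(cloud$ap_um[1], 20 * 10)
  expect_equal(cloud$dv_um[1], 40 * 10)
  expect_equal(cloud$ml_um[1], 50 * 10)
  # re-looking up the exported voxel reproduces the assignment
  for (i in seq_len(nrow(cloud))) {
    node <- lookup_region(b, c(cloud$ap_um[i], cloud$dv_um[i],
                               cloud$ml_um[i]) / 10)
    expect_equal(node$id, rec$assignments$id[i])
  }
  empty <- to_ccf3d(assign_regions(point_set(frame = "atlas"), b, sp), b)
  expect_equal(nrow(empty), 0)
})

test_that("Allen and Chon tallies of the same points have identical totals", {
  fx <- toy_fixture()
  allen <- fx$bundle
  chon <- toy_bundle("chon")
  ps <- fx$cell_points_atlas
  ta <- tally_regions(assign_regions(ps, allen, fx$slice_plane))
  tc <- tally_regions(assign_regions(ps, chon, fx$slice_plane))
  expect_equal(attr(ta, "total"), attr(tc, "total"))
  expect_equal(attr(ta, "total"), nrow(ps))
})

test_that("compare_atlases matches closed-form statistics", {
  b <- toy_bundle(); cb <- toy_bundle("chon")
  sp <- slice_plane("coronal", 0)
  mk_recs <- function(bundle, sizes, seed) {
    slc <- extract_slice(bundle, sp)
    inb <- which(slc$labels != 0, arr.ind = TRUE)
    withr::with_seed(seed, lapply(seq_along(sizes), function(i) {
      pick <- inb[sample.int(nrow(inb), sizes[i]), , drop = FALSE]
      assign_regions(point_set(pick[, 2] - 1, pick[, 1] - 1, frame = "atlas"),
                     bundle, sp, slice_id = sprintf("s%02d", i))
    }))
  }
  sizes <- c(30, 45, 12, 60, 25)
  ra <- mk_recs(b, sizes, 5)
  rc <- mk_recs(cb, sizes + c(2, -1, 3, 0, -4), 6)
  ta <- tally_regions(ra, "per_slice")
  tc <- tally_regions(rc, "per_slice")
  cmp <- compare_atlases(ta, tc)
  # independent Pearson oracle from the definition
  tot <- function(recs) vapply(recs, function(r) nrow(r$points), numeric(1))
  x <- tot(ra); y <- tot(rc)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cmp$pearson_r, r_oracle, tolerance = 1e-12)
  expect_equal(cmp$n_slices, 5)
  # paired t against stats::t.test on the same structure counts
  ns <- function(recs) vapply(recs, function(r)
    length(setdiff(unique(r$assignments$id), 0L)), numeric(1))
  if (stats::sd(ns(ra) - ns(rc)) > 0) {
    tt <- stats::t.test(ns(ra), ns(rc), paired = TRUE)
    expect_equal(cmp$t_stat, unname(tt$statistic))
  }
  # shared toy nomenclature: odd-indexed names coincide by construction
  expect_gte(cmp$name_overlap, 1)

  # identical tables: r = 1, t = 0
  same <- compare_atlases(ta, ta)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$t_stat, 0)

  expect_error(compare_atlases(ta[ta$slice_id == "s01", ],
                               tc[tc$slice_id == "s01", ]),
               class = "histoslice_insufficient_n")
})

test_that("per-slice cell lists and count tables write to CSV", {
  fx <- toy_fixture()
  rec <- assign_regions(fx$cell_points_atlas, fx$bundle, fx$slice_plane,
                        slice_id = "s1")
  d <- withr::local_tempdir()
  f1 <- file.path(d, "cells.csv")
  write_cell_regions(rec, f1)
  df <- readr::read_csv(f1, show_col_types = FALSE)
  expect_equal(nrow(df), 50)
  expect_true(all(c("slice_id", "x", "y", "structure_id", "acronym", "name")
                  %in% names(df)))
  f2 <- file.path(d, "counts.csv")
  write_region_counts(tally_regions(rec), f2)
  back <- readr::read_csv(f2, show_col_types = FALSE)
  expect_equal(sum(back$count), 50)
})
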