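# Synthetic fixtures: toy atlases, rendered slices with known deformation
# and known cell placements, and landmark sets with controlled noise. These
# stand in for real example images so the whole pipeline builds and tests
# without downloading an atlas. All randomness flows through withr::with_seed
# on the caller-supplied seed; no global RNG state is touched.

toy_region_names <- list(
  allen = c("toy isocortex", "toy thalamus", "toy hypothalamus",
            "toy midbrain", "toy pons", "toy medulla", "toy striatum",
            "toy pallidum", "toy hippocampus", "toy cerebellum",
            "toy olfactory areas", "toy septum", "toy amygdala",
            "toy habenula", "toy claustrum", "toy zona incerta",
            "toy superior colliculus", "toy inferior colliculus",
            "toy raphe", "toy locus coeruleus"),
  # odd indices share the Allen name (exact-name nomenclature overlap),
  # even indices get variant-specific nomenclature
  chon = c("toy isocortex", "toy dorsal thalamus", "toy hypothalamus",
           "toy mesencephalon", "toy pons", "toy myelencephalon",
           "toy striatum", "toy globus pallidus", "toy hippocampus",
           "toy cerebellar cortex", "toy olfactory areas",
           "toy lateral septum", "toy amygdala", "toy epithalamus",
           "toy claustrum", "toy subthalamus",
           "toy superior colliculus", "toy caudal colliculus",
           "toy raphe", "toy nucleus K")
)

#' Generate a toy atlas bundle
#'
#' Builds a small annotation volume of nested ellipsoidal regions inside an
#' ellipsoidal brain mask, with a matching structure tree (one root plus
#' one node per region). Region 1 is the outermost shell (the remaining
#' brain), regions 2..n nest successively deeper, so every brain voxel is
#' labeled — as in a real annotation volume. The `chon` variant uses the
#' same brain mask on the same grid but different region borders, ids
#' (101, 102, ...) and partially different nomenclature, emulating a second
#' delineation of the same reference space.
#'
#' @param seed integer seed; the same seed reproduces the volume bit-exactly.
#' @param shape volume shape `c(ap, dv, ml)`, each >= 20.
#' @param n_regions number of regions (1..20).
#' @param variant `"allen"` or `"chon"`.
#' @param voxel_size_um voxel size (default 10).
#' @return an [atlas_bundle].
#' @export
make_toy_atlas <- function(seed = 1, shape = c(60, 80, 100), n_regions = 4,
                           variant = c("allen", "chon"), voxel_size_um = 10) {
  variant <- match.arg(variant)
  if (any(shape < 20)) stopf("toy atlas shape must be at least 20 per axis")
  if (n_regions < 1 || n_regions > 20) stopf("n_regions must be in 1..20")
  step <- 0.8 / n_regions
  if (min(shape) * 0.45 * step < 2) {
    stopf("shape %s too small to nest %d regions",
          paste(shape, collapse = "x"), n_regions)
  }
  withr::with_seed(seed, {
    ctr <- (shape - 1) / 2
    semi <- 0.45 * shape
    ax <- seq_len(shape[1]) - 1
    dv <- seq_len(shape[2]) - 1
    ml <- seq_len(shape[3]) - 1
    # normalized squared radius field for an ellipsoid at ctr2/semi2
    rad2 <- function(ctr2, semi2) {
      a <- ((ax - ctr2[1]) / semi2[1])^2
      b <- ((dv - ctr2[2]) / semi2[2])^2
      c <- ((ml - ctr2[3]) / semi2[3])^2
      outer(outer(a, b, "+"), c, "+")
    }
    ann <- array(0L, shape)
    border_shift <- if (variant == "chon") -0.45 * step else 0
    for (k in seq_len(n_regions)) {
      s <- 1 - (k - 1) * step + if (k > 1) border_shift else 0
      jit <- runif(3, -0.015, 0.015)      # per-seed border variation
      cjit <- if (k > 1) runif(3, -1, 1) else c(0, 0, 0)
      inside <- rad2(ctr + cjit, semi * (s + jit)) <= 1
      ann[inside] <- k
    }
    ids <- if (variant == "chon") 100L + seq_len(n_regions) else seq_len(n_regions)
    ann[ann != 0] <- ids[ann[ann != 0]]
    root_id <- if (variant == "chon") 1000L else 900L
    nm <- toy_region_names[[variant]][seq_len(n_regions)]
    tree <- bind_rows(
      tibble(id = root_id, acronym = "root", name = "toy brain root",
             parent_id = NA_integer_),
      tibble(id = ids,
             acronym = paste0(if (variant == "chon") "c", "TR", seq_len(n_regions)),
             name = nm, parent_id = root_id))
    new_atlas_bundle(ann, tree, variant, voxel_size_um,
                     bregma_voxel = c(floor(shape[1] / 2), 0, floor(shape[3] / 2)))
  })
}

#' Construct planar transforms from known parameters
#'
#' Build a `planar_transform` directly from a 3x3 matrix — the
#' ground-truth deformations used by the synthetic fixtures and the
#' construct-and-recover tests.
#'
#' @param H 3x3 homography matrix (last row `c(0, 0, 1)` for affine).
#' @param family `"projective"` or `"affine"`.
#' @param sp optional [slice_plane].
#' @return a `planar_transform`.
#' @export
matrix_transform <- function(H, family = c("projective", "affine"), sp = NULL) {
  family <- match.arg(family)
  H <- matrix(as.numeric(H), 3, 3)
  structure(list(family = family, params = H / H[3, 3],
                 source_frame = "padded", target_frame = "atlas",
                 slice_plane = sp, landmarks = tibble(),
                 schema_version = "1.0", fit_residuals = numeric()),
            class = "planar_transform")
}

invert_matrix_transform <- function(tf) {
  matrix_transform(solve(matrix(unlist(tf$params), 3, 3)), tf$family,
                   tf$slice_plane)
}

# Pixels of `mask` at Chebyshev distance > margin from any FALSE pixel.
erode_mask <- function(mask, margin) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -margin:margin) for (dc in -margin:margin) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- mask[rs - dr, cs - dc]
    out <- out & sh
  }
  out
}

# 12 distinctive landmark positions on the outline of the brain mask of a
# label image: the farthest boundary pixel from the mask centroid in each
# of `n` evenly spaced directions.
mask_corner_landmarks <- function(labels, n = 12) {
  mask <- labels != 0
  edge <- mask & !erode_mask(mask, 1)
  idx <- which(edge, arr.ind = TRUE)
  ctr <- colMeans(idx)
  ang <- atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2])
  rad <- sqrt(rowSums(sweep(idx, 2, ctr)^2))
  targets <- seq(-pi, pi, length.out = n + 1)[seq_len(n)]
  pick <- vapply(targets, function(th) {
    d <- abs(atan2(sin(ang - th), cos(ang - th)))
    cand <- which(d < pi / n)
    if (!length(cand)) cand <- which.min(d)
    cand[which.max(rad[cand])]
  }, integer(1))
  # (x = col0, y = row0)
  cbind(x = idx[pick, 2] - 1, y = idx[pick, 1] - 1)
}

#' Render a synthetic slice with known ground truth
#'
#' The fixture generator behind every end-to-end test: it extracts the
#' requested atlas section, samples cell locations at least `margin` voxels
#' inside each requested region, maps them through the inverse of the
#' ground-truth transform and the inverse canvas geometry into a raw image
#' frame at `pixel_size_um`, renders the tissue silhouette plus Gaussian
#' cell blobs and sensor noise, and writes the same artifact set a real
#' experiment provides: a 16-bit TIFF, a FIJI-dialect coordinate CSV and a
#' landmark CSV with exact pairs on distinctive outline positions.
#'
#' @param bundle an [atlas_bundle] (typically [make_toy_atlas()]).
#' @param sp a [slice_plane].
#' @param cells_per_region named vector: region id -> number of cells.
#' @param true_transform ground-truth padded -> atlas `planar_transform`
#'   (default identity).
#' @param pixel_size_um raw image resolution (default 0.5 um/px, the
#'   resolution of typical example images).
#' @param seed integer seed; same seed gives byte-identical outputs.
#' @param dir output directory for TIFF/CSV artifacts.
#' @param name file stem for the artifacts.
#' @param margin minimum Chebyshev distance (voxels) of sampled cells from
#'   any region border (default 3).
#' @param n_landmarks number of landmark pairs (default 12, >= 10).
#' @return a `fixture_truth` list: `bundle`, `slice_plane`,
#'   `true_transform`, `cell_points_raw`, `cell_points_atlas`,
#'   `true_assignments`, `true_counts`, `landmarks`, `canvas_record`,
#'   `paths` (tiff, points_csv, landmarks_csv), `seed`.
#' @export
make_synthetic_slice <- function(bundle, sp, cells_per_region,
                                 true_transform = NULL, pixel_size_um = 0.5,
                                 seed = 1, dir = tempfile("fixture"),
                                 name = "slice", margin = 3,
                                 n_landmarks = 12) {
  if (is.null(true_transform)) true_transform <- matrix_transform(diag(3))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slc <- extract_slice(bundle, sp)
  canvas <- dim(slc$labels)
  f <- pixel_size_um / bundle$voxel_size_um
  up <- 1 / f
  if (abs(up - round(up)) > 1e-9) {
    stopf("pixel_size_um must divide the voxel size for fixture rendering")
  }
  up <- round(up)
  withr::with_seed(seed, {
    atlas_pts <- list()
    for (id in names(cells_per_region)) {
      idn <- as.integer(id)
      cnt <- cells_per_region[[id]]
      interior <- erode_mask(slc$labels == idn, margin)
      cand <- which(interior, arr.ind = TRUE)
      if (nrow(cand) < cnt) {
        stopf("region %s too small for %d cells (only %d interior pixels)",
              id, cnt, nrow(cand))
      }
      sel <- cand[sample.int(nrow(cand), cnt), , drop = FALSE]
      atlas_pts[[id]] <- tibble(
        x = sel[, 2] - 1 + runif(cnt, -0.3, 0.3),
        y = sel[, 1] - 1 + runif(cnt, -0.3, 0.3),
        true_id = idn)
    }
    apts <- bind_rows(atlas_pts)
    inv <- transform_xy(true_transform, apts$x, apts$y, inverse = TRUE)
    raw_x <- inv$x / f
    raw_y <- inv$y / f
    raw_dim <- canvas * up
    if (any(raw_x < 0 | raw_x > raw_dim[2] - 1 | raw_y < 0 | raw_y > raw_dim[1] - 1)) {
      stopf("true transform pushes cells outside the raw image; use a milder deformation")
    }
    # raw-frame tissue silhouette: padded-frame view of the atlas mask
    tissue_atlas <- (slc$labels != 0) * 1
    tissue_padded <- warp_image(tissue_atlas,
                                invert_matrix_transform(true_transform),
                                canvas)
    ri <- pmin(floor((seq_len(raw_dim[1]) - 1) / up) + 1, canvas[1])
    ci <- pmin(floor((seq_len(raw_dim[2]) - 1) / up) + 1, canvas[2])
    img <- 1500 * tissue_padded[ri, ci] + 200
    img <- img + matrix(rnorm(length(img), 0, 30), raw_dim[1], raw_dim[2])
    blob_r <- 2L * up %/% 2L + 6L
    kern_off <- expand.grid(dr = -blob_r:blob_r, dc = -blob_r:blob_r)
    kern_amp <- 12000 * exp(-(kern_off$dr^2 + kern_off$dc^2) / (2 * (up / 4 + 2)^2))
    for (i in seq_along(raw_x)) {
      rr <- round_half_up(raw_y[i]) + kern_off$dr
      cc <- round_half_up(raw_x[i]) + kern_off$dc
      keep <- in_bounds0(rr, raw_dim[1]) & in_bounds0(cc, raw_dim[2])
      pix <- cbind(rr[keep] + 1, cc[keep] + 1)
      img[pix] <- img[pix] + kern_amp[keep]
    }
    img <- pmin(pmax(img, 0), 65535)
    # landmarks on outline corners, exact under the true transform
    lm_atlas <- mask_corner_landmarks(slc$labels, n_landmarks)
    lm_inv <- transform_xy(true_transform, lm_atlas[, 1], lm_atlas[, 2],
                           inverse = TRUE)
    lms <- landmark_set(cbind(lm_inv$x, lm_inv$y), lm_atlas)
    paths <- list(
      tiff = file.path(dir, paste0(name, ".tif")),
      points_csv = file.path(dir, paste0(name, ".csv")),
      landmarks_csv = file.path(dir, paste0(name, "_landmarks.csv")))
    tiff::writeTIFF(round(img) / 65535, paths$tiff, bits.per.sample = 16L)
    readr::write_csv(tibble(` ` = seq_along(raw_x), X = raw_x, Y = raw_y),
                     paths$points_csv, progress = FALSE)
    write_landmarks(lms, paths$landmarks_csv)
    truth_nodes <- nodes_for_ids(bundle, apts$true_id)
    counts <- truth_nodes |>
      count(.data$id, .data$acronym, .data$name, name = "count") |>
      arrange(dplyr::desc(.data$count), .data$id)
    counts <- structure(counts, scope = "per_brain",
                        atlas_variant = bundle$variant,
                        total = sum(counts$count),
                        class = c("region_count_table", class(counts)))
    list(bundle = bundle, slice_plane = sp, true_transform = true_transform,
         cell_points_raw = point_set(raw_x, raw_y, frame = "raw",
                                     source_image = name),
         cell_points_atlas = point_set(apts$x, apts$y, frame = "atlas",
                                       source_image = name),
         true_assignments = truth_nodes,
         true_counts = counts, landmarks = lms,
         canvas_record = canvas_record(up, c(0, 0), canvas),
         paths = paths, seed = seed)
  })
}

#' Add landmark-click noise
#'
#' Adds isotropic Gaussian noise of standard deviation `sigma_px` to the
#' slice-side landmark coordinates only (atlas-side clicks are taken as the
#' reference), deterministically for a given seed. The expected Euclidean
#' displacement per landmark is `sigma_px * sqrt(pi / 2)`.
#'
#' @param lms a `landmark_set`.
#' @param sigma_px noise standard deviation per axis (>= 0, slice px).
#' @param seed integer seed.
#' @return a perturbed `landmark_set`.
#' @export
perturb_landmarks <- function(lms, sigma_px, seed = 1) {
  if (sigma_px < 0) stopf("sigma_px must be non-negative")
  if (sigma_px == 0) return(lms)
  withr::with_seed(seed, {
    n <- nrow(lms)
    landmark_set(cbind(lms$slice_x + rnorm(n, 0, sigma_px),
                       lms$slice_y + rnorm(n, 0, sigma_px)),
                 cbind(lms$atlas_x, lms$atlas_y), idx = lms$idx)
  })
}
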