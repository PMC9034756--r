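#' Landmark sets
#'
#' Numbered pairs of corresponding points between a padded slice image and
#' the atlas canvas, the headless counterpart of clicking matched landmarks
#' in two viewer windows. Stored as a tibble with columns
#' `idx, slice_x, slice_y, atlas_x, atlas_y` (pixel coordinates, 0-based,
#' x = column / y = row).
#'
#' @param slice_xy,atlas_xy two-column matrices or data frames of (x, y).
#' @param idx landmark numbers (default 1..n).
#' @return a `landmark_set` tibble.
#' @export
landmark_set <- function(slice_xy, atlas_xy, idx = NULL) {
  s <- as.matrix(slice_xy); a <- as.matrix(atlas_xy)
  if (nrow(s) != nrow(a)) stopf("slice and atlas landmark counts differ")
  if (!all(is.finite(s)) || !all(is.finite(a))) stopf("landmarks must be finite")
  if (anyDuplicated(s[, 1:2, drop = FALSE])) {
    stopf("duplicated slice-side landmark points")
  }
  out <- tibble(idx = idx %||% seq_len(nrow(s)),
                slice_x = s[, 1], slice_y = s[, 2],
                atlas_x = a[, 1], atlas_y = a[, 2])
  class(out) <- c("landmark_set", class(out))
  out
}

#' Read / write landmark CSV files
#'
#' CSV with columns `idx, slice_x, slice_y, atlas_x, atlas_y`; the file
#' contract that replaces interactive landmark clicking.
#'
#' @param path CSV path; `lm` a `landmark_set`.
#' @return a `landmark_set` (read) or `path` invisibly (write).
#' @export
read_landmarks <- function(path) {
  assert_file_exists(path, "landmark file")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("slice_x", "slice_y", "atlas_x", "atlas_y")
  if (!all(need %in% names(df))) {
    stopf("landmark file %s needs columns %s", basename(path),
          paste(c("idx", need), collapse = ", "))
  }
  landmark_set(df[c("slice_x", "slice_y")], df[c("atlas_x", "atlas_y")],
               idx = df$idx %||% seq_len(nrow(df)))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  readr::write_csv(as_tibble(lm), path, progress = FALSE)
  invisible(path)
}

family_minimum <- function(family) {
  switch(family, affine = 3L, projective = 4L, thin_plate_spline = 4L)
}

# Hartley-normalization similarity: translate centroid to origin, scale mean
# distance to sqrt(2). Returns 3x3 matrix.
norm_similarity <- function(xy) {
  ctr <- colMeans(xy)
  d <- sqrt(rowSums(sweep(xy, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
}

apply_h <- function(H, x, y) {
  w <- H[3, 1] * x + H[3, 2] * y + H[3, 3]
  list(x = (H[1, 1] * x + H[1, 2] * y + H[1, 3]) / w,
       y = (H[2, 1] * x + H[2, 2] * y + H[2, 3]) / w,
       w = w)
}

fit_affine_matrix <- function(src, dst) {
  X <- cbind(src, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    stopf("degenerate landmark configuration (collinear points) for affine fit",
          class = "histoslice_degenerate")
  }
  beta <- qr.coef(qrX, dst)            # 3 x 2
  rbind(t(beta), c(0, 0, 1))
}

fit_projective_matrix <- function(src, dst) {
  Ts <- norm_similarity(src); Td <- norm_similarity(dst)
  sn <- apply_h(Ts, src[, 1], src[, 2])
  dn <- apply_h(Td, dst[, 1], dst[, 2])
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(sn$x, sn$y, 1, 0, 0, 0,
                                 -dn$x * sn$x, -dn$x * sn$y, -dn$x)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, sn$x, sn$y, 1,
                                 -dn$y * sn$x, -dn$y * sn$y, -dn$y)
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1]) {
    stopf("degenerate landmark configuration for projective fit",
          class = "histoslice_degenerate")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  H
}

tps_kernel <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2) / 2)  # r^2 log r

fit_tps_side <- function(src, dst) {
  n <- nrow(src)
  d2 <- as.matrix(stats::dist(src))^2
  K <- tps_kernel(d2)
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stopf("degenerate landmark configuration for thin-plate spline fit",
          class = "histoslice_degenerate"))
  list(ctrl = src, w = sol[seq_len(n), , drop = FALSE],
       a = sol[n + 1:3, , drop = FALSE])
}

tps_apply <- function(side, x, y) {
  d2 <- outer(x, side$ctrl[, 1], "-")^2 + outer(y, side$ctrl[, 2], "-")^2
  U <- tps_kernel(d2)
  list(x = side$a[1, 1] + side$a[2, 1] * x + side$a[3, 1] * y + U %*% side$w[, 1],
       y = side$a[1, 2] + side$a[2, 2] * x + side$a[3, 2] * y + U %*% side$w[, 2])
}

#' Fit a planar transform from landmark pairs
#'
#' Least-squares fit of a 2D geometric transform mapping padded-slice
#' coordinates onto the atlas canvas. Families: `affine` (6 parameters,
#' minimum 3 landmarks), `projective` (homography, 8 parameters, minimum 4;
#' the default, matching the homography-like landmark workflow the pipeline
#' descends from), and `thin_plate_spline` (landmark-interpolating, minimum
#' 4, regularization 0 so landmarks are reproduced exactly; a reverse
#' spline atlas -> slice is fitted alongside for image resampling). With
#' `strict = TRUE` (the default) at least 10 landmarks are required — the
#' recommended minimum for reliable registration — and fewer is an error;
#' pass `strict = FALSE` to override.
#'
#' @param landmarks a `landmark_set`.
#' @param family transform family.
#' @param sp optional [slice_plane] embedded in the transform for
#'   provenance.
#' @param strict enforce the 10-landmark minimum (default `TRUE`).
#' @return a `planar_transform` with per-landmark `fit_residuals`
#'   (Euclidean distances in atlas px).
#' @export
fit_transform <- function(landmarks,
                          family = c("projective", "affine", "thin_plate_spline"),
                          sp = NULL, strict = TRUE) {
  family <- match.arg(family)
  lm <- as_tibble(landmarks)
  n <- nrow(lm)
  if (n < family_minimum(family)) {
    stopf("%s fit needs at least %d landmarks, got %d (under-determined)",
          family, family_minimum(family), n,
          class = "histoslice_underdetermined")
  }
  if (strict && n < 10L) {
    stopf(paste("strict mode requires at least 10 landmarks (the recommended",
                "minimum for reliable registration); got %d.",
                "Pass strict = FALSE to override."), n,
          class = "histoslice_strict_landmarks")
  }
  src <- cbind(lm$slice_x, lm$slice_y)
  dst <- cbind(lm$atlas_x, lm$atlas_y)
  params <- switch(family,
    affine = fit_affine_matrix(src, dst),
    projective = fit_projective_matrix(src, dst),
    thin_plate_spline = list(fwd = fit_tps_side(src, dst),
                             rev = fit_tps_side(dst, src)))
  tf <- structure(list(family = family, params = params,
                       source_frame = "padded", target_frame = "atlas",
                       slice_plane = sp, landmarks = lm,
                       schema_version = "1.0"),
                  class = "planar_transform")
  pred <- transform_xy(tf, src[, 1], src[, 2])
  tf$fit_residuals <- sqrt((pred$x - dst[, 1])^2 + (pred$y - dst[, 2])^2)
  tf
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("<planar_transform %s: %d landmarks, rmse %.4g px, max residual %.4g px>\n",
              x$family, length(x$fit_residuals),
              sqrt(mean(x$fit_residuals^2)), max(x$fit_residuals)))
  invisible(x)
}

# forward mapping of bare coordinates (padded -> atlas)
transform_xy <- function(tf, x, y, inverse = FALSE) {
  if (tf$family == "thin_plate_spline") {
    side <- if (inverse) tf$params$rev else tf$params$fwd
    p <- tps_apply(side, x, y)
    return(list(x = as.numeric(p$x), y = as.numeric(p$y)))
  }
  H <- matrix(unlist(tf$params), 3, 3)
  if (inverse) H <- solve(H)
  p <- apply_h(H, x, y)
  list(x = p$x, y = p$y, w = p$w)
}

#' Warp a point set through a fitted transform
#'
#' Maps every point through the same forward transform used for the image
#' (the "identical way" contract between image warping and cell-coordinate
#' warping). Count, order and any extra columns are preserved; points may
#' land outside the brain and are kept — they are tallied as outside later.
#'
#' @param ps `point_set` in the `padded` frame.
#' @param tf a fitted `planar_transform`.
#' @return `point_set` in the `atlas` frame.
#' @export
warp_points <- function(ps, tf) {
  assert_frame(ps, "padded", "warp_points")
  if (!nrow(ps)) return(with_coords(ps, numeric(), numeric(), frame = "atlas"))
  p <- transform_xy(tf, ps$x, ps$y)
  with_coords(ps, p$x, p$y, frame = "atlas")
}

#' Warp an image onto the atlas canvas
#'
#' Inverse-mapped resampling: every output pixel of the atlas canvas is
#' pulled from the padded image through the inverse transform, with
#' bilinear interpolation of intensities. Pixels mapping outside the source
#' image — or where a projective transform is not invertible (vanishing
#' homogeneous denominator) — are set to 0; the latter are counted in a
#' warning.
#'
#' @param image matrix or rows x cols x channels array in the padded frame.
#' @param tf a fitted `planar_transform`.
#' @param output_shape `c(rows, cols)` of the atlas canvas.
#' @return warped numeric array of shape `output_shape` (x channels).
#' @export
warp_image <- function(image, tf, output_shape) {
  multi <- length(dim(image)) == 3L
  src_dim <- dim(image)[1:2]
  nr <- output_shape[1]; nc <- output_shape[2]
  gx <- rep(seq_len(nc) - 1, each = nr)
  gy <- rep(seq_len(nr) - 1, times = nc)
  p <- transform_xy(tf, gx, gy, inverse = TRUE)
  bad <- if (!is.null(p$w)) !is.finite(p$x) | !is.finite(p$y) else
    rep(FALSE, length(gx))
  if (tf$family == "projective") {
    # denominator of the *inverse* mapping may vanish; detect via non-finite
    n_bad <- sum(bad)
    if (n_bad > 0) warn(sprintf("%d output pixels not invertible; set to 0", n_bad))
  }
  sample_bilinear <- function(ch) {
    x <- p$x; y <- p$y
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    inside <- !bad & x0 >= 0 & y0 >= 0 & x0 <= src_dim[2] - 1 & y0 <= src_dim[1] - 1
    gi <- function(r, c) {
      r <- pmin(pmax(r, 0), src_dim[1] - 1)
      c <- pmin(pmax(c, 0), src_dim[2] - 1)
      ch[cbind(r + 1, c + 1)]
    }
    out <- numeric(length(x))
    i <- which(inside)
    if (length(i)) {
      out[i] <- (1 - fx[i]) * (1 - fy[i]) * gi(y0[i], x0[i]) +
                fx[i] * (1 - fy[i]) * gi(y0[i], x0[i] + 1) +
                (1 - fx[i]) * fy[i] * gi(y0[i] + 1, x0[i]) +
                fx[i] * fy[i] * gi(y0[i] + 1, x0[i] + 1)
    }
    matrix(out, nr, nc)
  }
  if (!multi) return(sample_bilinear(image))
  out <- array(0, c(nr, nc, dim(image)[3]))
  for (k in seq_len(dim(image)[3])) out[, , k] <- sample_bilinear(image[, , k])
  out
}

#' Save, load and re-apply transforms
#'
#' Transforms serialize to JSON with an explicit schema version (the
#' "geometric transformation file"); `load_transform(save_transform(tf))`
#' reproduces the mapping bit-exactly. `apply_saved_transform()` warps a
#' point set with a previously saved transform, so a second channel's cell
#' counts reuse a registration without refitting.
#'
#' @param tf a `planar_transform`; `path` a JSON path; `ps` a `point_set`
#'   in the padded frame.
#' @return `save_transform`: `path` invisibly. `load_transform`: the
#'   transform. `apply_saved_transform`: a `point_set` in the atlas frame.
#' @export
save_transform <- function(tf, path) {
  # numeric blocks are written as 17-significant-digit strings so every
  # IEEE double round-trips bit-exactly through the JSON text
  pack <- function(m) list(dim = dim(m), data = sprintf("%.17g", m))
  obj <- list(schema_version = tf$schema_version, family = tf$family,
              source_frame = tf$source_frame, target_frame = tf$target_frame,
              fit_residuals = tf$fit_residuals,
              slice_plane = if (!is.null(tf$slice_plane)) unclass(tf$slice_plane),
              landmarks = as.data.frame(tf$landmarks),
              params = if (tf$family == "thin_plate_spline") {
                lapply(tf$params, function(s)
                  list(ctrl = pack(s$ctrl), w = pack(s$w), a = pack(s$a)))
              } else list(matrix = pack(tf$params)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  assert_file_exists(path, "transform file")
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stopf("corrupted transform file: %s (%s)",
                                            path, conditionMessage(e),
                                            class = "histoslice_corrupt_file"))
  if (is.null(obj$schema_version) || is.null(obj$family) || is.null(obj$params)) {
    stopf("corrupted transform file: %s (missing required fields)", path,
          class = "histoslice_corrupt_file")
  }
  if (!identical(obj$schema_version, "1.0")) {
    stopf("unsupported transform schema version '%s'", obj$schema_version,
          class = "histoslice_version_mismatch")
  }
  unpack <- function(p) {
    x <- as.numeric(p$data)
    if (!is.null(p$dim) && length(p$dim)) dim(x) <- unlist(p$dim)
    x
  }
  params <- if (obj$family == "thin_plate_spline") {
    lapply(obj$params, function(s)
      list(ctrl = unpack(s$ctrl), w = unpack(s$w), a = unpack(s$a)))
  } else matrix(unpack(obj$params$matrix), 3, 3)
  sp <- if (!is.null(obj$slice_plane$plane)) {
    slice_plane(obj$slice_plane$plane, obj$slice_plane$position_mm,
                obj$slice_plane$dv_tilt_deg, obj$slice_plane$ml_tilt_deg)
  }
  structure(list(family = obj$family, params = params,
                 source_frame = obj$source_frame, target_frame = obj$target_frame,
                 slice_plane = sp, landmarks = as_tibble(obj$landmarks),
                 schema_version = obj$schema_version,
                 fit_residuals = as.numeric(obj$fit_residuals)),
            class = "planar_transform")
}

#' @rdname save_transform
#' @export
apply_saved_transform <- function(path, ps) {
  warp_points(ps, load_transform(path))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted planar transform
#'
#' One row per parameter: homography entries `h11..h33` for matrix
#' families, affine/weight coefficients per output axis for thin-plate
#' splines.
#'
#' @param x a `planar_transform`.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`.
#' @method tidy planar_transform
#' @export
tidy.planar_transform <- function(x, ...) {
  if (x$family == "thin_plate_spline") {
    f <- x$params$fwd
    n <- nrow(f$ctrl)
    tibble(term = c(paste0("a", 0:2, "_x"), paste0("a", 0:2, "_y"),
                    paste0("w", seq_len(n), "_x"), paste0("w", seq_len(n), "_y")),
           estimate = c(f$a[, 1], f$a[, 2], f$w[, 1], f$w[, 2]))
  } else {
    H <- matrix(unlist(x$params), 3, 3)
    tibble(term = paste0("h", rep(1:3, each = 3), rep(1:3, 3)),
           estimate = as.vector(t(H)))
  }
}

#' Summarize a fitted planar transform
#'
#' @param x a `planar_transform`.
#' @param ... unused.
#' @return one-row tibble: family, landmark count, residual RMSE / max
#'   (atlas px).
#' @method glance planar_transform
#' @export
glance.planar_transform <- function(x, ...) {
  tibble(family = x$family, n_landmarks = length(x$fit_residuals),
         rmse = sqrt(mean(x$fit_residuals^2)),
         max_residual = max(x$fit_residuals))
}
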