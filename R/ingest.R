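#' Read a slice image
#'
#' Loads a `.tif`/`.tiff` histology image with its declared pixel size and
#' channel names. Multi-page TIFFs map pages to channels; a single page with
#' an RGB(A) third dimension maps samples to channels. Images must already
#' be in anatomically correct orientation; only shape and metadata are
#' validated here.
#'
#' @param path TIFF file path.
#' @param pixel_size_um physical pixel size in microns (> 0).
#' @param channel_names character vector naming the channels; length must
#'   match the channel count (default: `ch1`, `ch2`, ...).
#' @return a `raw_slice`: list with `image` (rows x cols x channels integer
#'   array), `pixel_size_um`, `channel_names`, `source_path`.
#' @export
read_slice_image <- function(path, pixel_size_um, channel_names = NULL) {
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stopf("slice images must be .tif or .tiff files, got: %s", basename(path),
          class = "histoslice_format_error")
  }
  assert_file_exists(path, "image")
  if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0) {
    stopf("pixel_size_um must be a positive scalar")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  to_channels <- function(pg) {
    if (length(dim(pg)) == 3L) lapply(seq_len(dim(pg)[3]), function(k) pg[, , k])
    else list(pg)
  }
  chans <- unlist(lapply(pages, to_channels), recursive = FALSE)
  img <- array(0L, c(dim(chans[[1]]), length(chans)))
  for (k in seq_along(chans)) img[, , k] <- as.integer(chans[[k]])
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_along(chans))
  if (length(channel_names) != length(chans)) {
    stopf("image has %d channels but %d channel names were given",
          length(chans), length(channel_names))
  }
  structure(list(image = img, pixel_size_um = pixel_size_um,
                 channel_names = channel_names, source_path = path),
            class = "raw_slice")
}

#' @export
print.raw_slice <- function(x, ...) {
  cat(sprintf("<raw_slice %dx%d, %d channel(s) [%s] @ %g um/px>\n",
              dim(x$image)[1], dim(x$image)[2], dim(x$image)[3],
              paste(x$channel_names, collapse = ", "), x$pixel_size_um))
  invisible(x)
}

# Sparse 1-D area-average aggregation matrix mapping n_in input pixels to
# n_out output pixels under scale factor f = n_out / n_in (f <= 1). Each
# input pixel covers [j, j+1) raw units and overlaps at most two output
# pixels of width 1/f; weights are overlap fractions, so rows sum to 1 and
# an integer 1/f reduces to the exact block mean.
area_average_matrix <- function(n_in, n_out) {
  f <- n_out / n_in
  j <- seq_len(n_in) - 1
  o1 <- pmin(floor(j * f), n_out - 1)
  o2 <- pmin(floor((j + 1) * f - 1e-12), n_out - 1)
  w1 <- pmin(j + 1, (o1 + 1) / f) - j
  i_idx <- c(o1, o2[o2 > o1])
  j_idx <- c(j, j[o2 > o1])
  w <- c(w1, (j + 1 - (o1 + 1) / f)[o2 > o1])
  Matrix::sparseMatrix(i = i_idx + 1, j = j_idx + 1, x = w * f,
                       dims = c(n_out, n_in))
}

block_mean_rows <- function(m, k) {
  nr <- nrow(m) %/% k
  dim(m) <- c(k, nr * ncol(m))
  matrix(colMeans(m), nr)
}

downsample_channel <- function(m, f) {
  n_out_r <- round_half_up(nrow(m) * f)
  n_out_c <- round_half_up(ncol(m) * f)
  k <- 1 / f
  if (abs(k - round(k)) < 1e-12 && nrow(m) == n_out_r * round(k) &&
      ncol(m) == n_out_c * round(k)) {
    # integer factor: area average reduces to the exact block mean
    return(t(block_mean_rows(t(block_mean_rows(m, round(k))), round(k))))
  }
  A <- area_average_matrix(nrow(m), n_out_r)
  B <- area_average_matrix(ncol(m), n_out_c)
  as.matrix(A %*% m %*% Matrix::t(B))
}

# Linear contrast rescale of one channel. spec: list(low=, high=) quantiles
# in [0,1], or list(min=, max=) absolute intensity bounds. Output spans the
# input dtype range implied by max_val.
apply_contrast <- function(m, spec, max_val) {
  if (is.null(spec)) return(m)
  if (!is.null(spec$low) || !is.null(spec$high)) {
    qs <- quantile(m, c(spec$low %||% 0, spec$high %||% 1), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  } else {
    lo <- spec$min %||% 0; hi <- spec$max %||% max_val
  }
  if (hi <= lo) hi <- lo + 1
  pmax(pmin((m - lo) / (hi - lo) * max_val, max_val), 0)
}

#' Downsample to atlas resolution and pad to the registration canvas
#'
#' The pre-processing step of the pipeline: each channel gets an optional
#' linear contrast adjustment, is resampled from its acquisition resolution
#' to the atlas voxel size by area averaging (scale factor
#' `f = pixel_size_um / atlas_voxel_um`), and is then centred on the fixed
#' registration canvas with symmetric zero padding (800 x 1140 pixels for
#' the coronal Allen canvas at 10 um). Cell coordinates are transformed
#' analytically by the same geometry, `(x, y) -> (x * f + pad_col,
#' y * f + pad_row)`, so the mapping applied to points is identical to the
#' one applied to the image while preserving point multiplicity. The
#' returned `canvas_record` makes the mapping exactly invertible.
#'
#' @param slice a `raw_slice` from [read_slice_image()].
#' @param points optional `point_set` in the `raw` frame from the same
#'   image (its `source_image` must match the image basename when both are
#'   known).
#' @param atlas_voxel_um target resolution (default 10 um/px).
#' @param canvas canvas shape `c(rows, cols)` (default `c(800, 1140)`).
#' @param contrast optional contrast spec: a single list applied to all
#'   channels or a list per channel; each either
#'   `list(low =, high =)` quantiles or `list(min =, max =)` bounds.
#' @param bit_depth bit depth used for the contrast intensity range
#'   (default inferred: 8 if the data maximum fits, else 16).
#' @return list with `image` (canvas-sized numeric array), `points`
#'   (`point_set`, frame `padded`; `NULL` when no points given) and
#'   `canvas_record` (`scale_factor` = raw px per atlas px, `pad_offset`
#'   = (row, col) of the image origin on the canvas, `canvas_shape`).
#' @export
preprocess <- function(slice, points = NULL, atlas_voxel_um = 10,
                       canvas = c(800, 1140), contrast = NULL,
                       bit_depth = NULL) {
  stopifnot(inherits(slice, "raw_slice"))
  if (slice$pixel_size_um > atlas_voxel_um) {
    stopf("raw pixel size (%g um) must not exceed the atlas voxel size (%g um)",
          slice$pixel_size_um, atlas_voxel_um)
  }
  if (!is.null(points)) {
    assert_frame(points, "raw", "preprocess")
    src <- attr(points, "source_image")
    img_src <- sub("\\.[^.]+$", "", basename(slice$source_path))
    if (!is.na(src) && nzchar(img_src) && img_src != "" && src != img_src) {
      stopf("point set source '%s' does not match image '%s'", src, img_src,
            class = "histoslice_pairing_error")
    }
  }
  f <- slice$pixel_size_um / atlas_voxel_um
  if (is.null(bit_depth)) bit_depth <- if (max(slice$image) <= 255) 8L else 16L
  max_val <- 2^bit_depth - 1
  nch <- dim(slice$image)[3]
  cspec <- if (is.null(contrast)) vector("list", nch)
           else if (!is.null(names(contrast))) rep(list(contrast), nch)
           else rep_len(contrast, nch)
  small <- lapply(seq_len(nch), function(k) {
    ch <- apply_contrast(slice$image[, , k], cspec[[k]], max_val)
    downsample_channel(ch, f)
  })
  hr <- nrow(small[[1]]); wc <- ncol(small[[1]])
  if (hr > canvas[1] || wc > canvas[2]) {
    stopf("downsampled image (%dx%d) exceeds the %dx%d canvas",
          hr, wc, canvas[1], canvas[2])
  }
  pad_r <- (canvas[1] - hr) %/% 2
  pad_c <- (canvas[2] - wc) %/% 2
  out <- array(0, c(canvas[1], canvas[2], nch))
  for (k in seq_len(nch)) {
    out[pad_r + seq_len(hr), pad_c + seq_len(wc), k] <- small[[k]]
  }
  rec <- canvas_record(scale_factor = 1 / f, pad_offset = c(pad_r, pad_c),
                       canvas_shape = as.integer(canvas))
  pts <- NULL
  if (!is.null(points)) {
    pts <- with_coords(points, points$x * f + pad_c, points$y * f + pad_r,
                       frame = "padded")
  }
  list(image = out, points = pts, canvas_record = rec)
}

#' Canvas geometry record
#'
#' Records the exact downsample-and-pad geometry of [preprocess()] so raw
#' coordinates can be recovered: `scale_factor` raw pixels per atlas pixel,
#' `pad_offset` (row, col) of the downsampled image origin on the canvas,
#' and the canvas shape.
#'
#' @param scale_factor raw px per atlas px (> 0).
#' @param pad_offset integer `c(row, col)`, both >= 0.
#' @param canvas_shape integer `c(rows, cols)`.
#' @return a `canvas_record`.
#' @export
canvas_record <- function(scale_factor, pad_offset, canvas_shape) {
  if (scale_factor <= 0) stopf("scale_factor must be positive")
  if (any(pad_offset < 0)) stopf("pad offsets must be non-negative")
  structure(list(scale_factor = scale_factor,
                 pad_offset = as.numeric(pad_offset),
                 canvas_shape = as.integer(canvas_shape)),
            class = "canvas_record")
}

#' Map padded-frame points back to raw acquisition coordinates
#'
#' Exact inverse of the point mapping performed by [preprocess()].
#'
#' @param ps `point_set` in the `padded` frame.
#' @param record the `canvas_record` from the same [preprocess()] call.
#' @return `point_set` in the `raw` frame.
#' @export
unpad_points <- function(ps, record) {
  assert_frame(ps, "padded", "unpad_points")
  with_coords(ps,
              (ps$x - record$pad_offset[2]) * record$scale_factor,
              (ps$y - record$pad_offset[1]) * record$scale_factor,
              frame = "raw")
}

#' Serialize / restore a canvas record as a JSON side-car
#' @param record a `canvas_record`; `path` a JSON file path.
#' @return `path` (write) or a `canvas_record` (read).
#' @export
write_canvas_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_canvas_record
#' @export
read_canvas_record <- function(path) {
  x <- jsonlite::fromJSON(path)
  canvas_record(x$scale_factor, x$pad_offset, x$canvas_shape)
}
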