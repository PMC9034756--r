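#' Cell-coordinate point sets
#'
#' A point set is a tibble of counted-cell coordinates with one row per cell.
#' Coordinates are continuous pixel positions with `x` = column and `y` = row,
#' origin at the top-left pixel (0-based), matching FIJI's multi-point
#' "measure" output on an uncalibrated image. Duplicate coordinates are kept:
#' two cells counted at the same pixel remain two rows throughout the
#' pipeline.
#'
#' The `frame` attribute records which coordinate frame the points live in
#' and may only change through the documented operations:
#' `raw` (acquisition pixels) -> `padded` (atlas-resolution canvas, via
#' [preprocess()]) -> `atlas` (registered canvas, via [warp_points()]) ->
#' `ccf3d` (micron atlas space, via [to_ccf3d()]).
#'
#' @param x,y numeric coordinate vectors (equal length).
#' @param label optional per-point grouping tag (e.g. imaging channel).
#' @param frame coordinate frame tag.
#' @param source_image source image identifier (basename pairing key).
#' @return a `point_set` tibble with columns `x`, `y` and optionally `label`.
#' @export
point_set <- function(x = numeric(), y = numeric(), label = NULL,
                      frame = c("raw", "downsampled", "padded", "atlas", "ccf3d"),
                      source_image = NA_character_) {
  frame <- match.arg(frame)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y)))) {
    stopf("point coordinates must be finite")
  }
  out <- tibble(x = x, y = y)
  if (!is.null(label)) out$label <- rep_len(label, nrow(out))
  new_point_set(out, frame = frame, source_image = source_image)
}

new_point_set <- function(df, frame, source_image = NA_character_,
                          edit_log = NULL) {
  structure(as_tibble(df),
            frame = frame,
            source_image = source_image,
            edit_log = edit_log,
            class = c("point_set", class(as_tibble(df))))
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set: %d points, frame = %s>\n", nrow(x), point_frame(x)))
  NextMethod()
}

#' Coordinate frame of a point set
#' @param ps a `point_set`.
#' @return frame tag string.
#' @export
point_frame <- function(ps) attr(ps, "frame") %||% "raw"

assert_frame <- function(ps, expected, op) {
  if (!identical(point_frame(ps), expected)) {
    stopf("%s expects points in the '%s' frame, got '%s'",
          op, expected, point_frame(ps), class = "histoslice_frame_error")
  }
  invisible(ps)
}

# Rebuild a point_set around transformed coordinates, preserving extra
# columns, attributes and row order.
with_coords <- function(ps, x, y, frame = point_frame(ps)) {
  df <- as_tibble(ps)
  df$x <- as.numeric(x)
  df$y <- as.numeric(y)
  new_point_set(df, frame = frame,
                source_image = attr(ps, "source_image"),
                edit_log = attr(ps, "edit_log"))
}

#' Read cell coordinates from a counting export
#'
#' Parses the three coordinate-file dialects produced by manual cell
#' counting: `fiji_csv` (FIJI "measure" CSV; any columns are accepted as long
#' as headers `X` and `Y` are present), `photoshop_txt` (Photoshop
#' count-tool text export, converted internally), and `plain_xy_csv`
#' (two columns `x,y`). One point per row, order and multiplicity preserved;
#' an empty file yields an empty point set.
#'
#' @param path coordinate file.
#' @param dialect one of `"fiji_csv"`, `"photoshop_txt"`, `"plain_xy_csv"`.
#' @param calibrated_um if the FIJI export was calibrated to microns, the
#'   pixel size in microns used to convert back to pixel units (default
#'   `NULL`: coordinates are already pixels).
#' @param label optional per-point tag (e.g. channel name).
#' @return a `point_set` in the `raw` frame.
#' @export
read_points <- function(path, dialect = c("fiji_csv", "photoshop_txt", "plain_xy_csv"),
                        calibrated_um = NULL, label = NULL) {
  dialect <- match.arg(dialect)
  assert_file_exists(path, "coordinate file")
  src <- sub("\\.[^.]+$", "", basename(path))
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(point_set(frame = "raw", source_image = src))
  }
  if (dialect == "photoshop_txt") {
    xy <- parse_photoshop_txt(path)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          name_repair = "minimal")
    nm <- names(df)
    pick <- function(want) {
      hit <- which(nm == want | toupper(nm) == toupper(want))
      if (!length(hit)) stopf("coordinate file %s lacks required column '%s'",
                              basename(path), want)
      hit[1]
    }
    if (dialect == "fiji_csv") {
      xy <- tibble(x = df[[pick("X")]], y = df[[pick("Y")]])
    } else {
      xy <- tibble(x = df[[pick("x")]], y = df[[pick("y")]])
    }
  }
  if (!is.numeric(xy$x) || !is.numeric(xy$y) || anyNA(xy$x) || anyNA(xy$y)) {
    stopf("non-numeric coordinates in %s", basename(path))
  }
  if (!is.null(calibrated_um)) {
    xy$x <- xy$x / calibrated_um
    xy$y <- xy$y / calibrated_um
  }
  point_set(xy$x, xy$y, label = label, frame = "raw", source_image = src)
}

# Photoshop count-tool exports a text table with per-point rows; the numeric
# X and Y fall in two whitespace/tab separated columns whose header row
# contains the tokens "X" and "Y" (mirrors the upstream importXY conversion
# to csv).
parse_photoshop_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(tibble(x = numeric(), y = numeric()))
  toks <- strsplit(trimws(lines), "[\t,;]+|\\s{1,}")
  header <- toupper(toks[[1]])
  xi <- which(header == "X")[1]
  yi <- which(header == "Y")[1]
  if (is.na(xi) || is.na(yi)) {
    # headerless export: take the first two numeric columns
    xi <- 1L; yi <- 2L; body <- toks
  } else {
    body <- toks[-1]
  }
  if (!length(body)) return(tibble(x = numeric(), y = numeric()))
  x <- suppressWarnings(as.numeric(vapply(body, `[`, "", xi)))
  y <- suppressWarnings(as.numeric(vapply(body, `[`, "", yi)))
  if (anyNA(x) || anyNA(y)) stopf("non-numeric coordinates in %s", basename(path))
  tibble(x = x, y = y)
}

#' Rasterize a point set to a binary occupancy mask
#'
#' Builds the binary-matrix form of a point set (TRUE where at least one
#' point rounds into the pixel). Provided for visual parity with ROI-matrix
#' style workflows; the quantification path works on the coordinates
#' themselves because the mask form collapses multiplicity.
#'
#' @param ps a `point_set`.
#' @param shape `c(rows, cols)` of the target mask.
#' @return logical matrix of dimension `shape`.
#' @export
points_to_mask <- function(ps, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (!nrow(ps)) return(m)
  r <- round_half_up(ps$y)
  c <- round_half_up(ps$x)
  if (any(!in_bounds0(r, shape[1])) || any(!in_bounds0(c, shape[2]))) {
    stopf("point outside mask shape %dx%d after rounding", shape[1], shape[2])
  }
  m[cbind(r + 1L, c + 1L)] <- TRUE
  m
}
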