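#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 imap pmap keep
#' @importFrom stats rnorm runif setNames cor t.test sd quantile
NULL

# Round half away from zero on the positive axis (0.5 -> 1), used everywhere a
# continuous pixel coordinate is committed to a pixel index.
round_half_up <- function(x) floor(x + 0.5)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ..., class = NULL) {
  abort(sprintf(fmt, ...), class = c(class, "histoslice_error"))
}

assert_file_exists <- function(path, what = "file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stopf("%s not found: %s", what, paste(path, collapse = ", "),
          class = "histoslice_missing_file")
  }
  invisible(path)
}

# 0-based in-bounds test for voxel/pixel indices
in_bounds0 <- function(i, n) !is.na(i) & i >= 0 & i <= (n - 1)
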