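# Minimal readers/writers for the two volume container formats the pipeline
# accepts: NPY (numpy .npy, format version 1.0/2.0) and NRRD (raw or gzip
# encoded). Only the subset needed for annotation/template volumes is
# supported: numeric scalar dtypes, C or Fortran order, little endian.

npy_dtypes <- list(
  "|u1" = list(what = "integer",  size = 1L, signed = FALSE),
  "|i1" = list(what = "integer",  size = 1L, signed = TRUE),
  "<u2" = list(what = "integer",  size = 2L, signed = FALSE),
  "<i2" = list(what = "integer",  size = 2L, signed = TRUE),
  "<i4" = list(what = "integer",  size = 4L, signed = TRUE),
  "<u4" = list(what = "numeric",  size = 4L, signed = FALSE),
  "<i8" = list(what = "numeric",  size = 8L, signed = TRUE),
  "<f4" = list(what = "double",   size = 4L, signed = TRUE),
  "<f8" = list(what = "double",   size = 8L, signed = TRUE)
)

#' Read a numpy array file
#'
#' Reads a `.npy` file (format 1.0 or 2.0) into an R array. Supports little
#' endian scalar dtypes and both C and Fortran memory order; the returned
#' array always uses R's column-major layout with the declared numpy shape.
#'
#' @param path path to a `.npy` file.
#' @return numeric/integer array with the file's shape.
#' @export
read_npy <- function(path) {
  assert_file_exists(path, "NPY file")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stopf("not an NPY file (bad magic): %s", path)
  }
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  hlen <- if (ver[1] >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_txt <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_txt), ",")[[1]])
  if (length(shape) == 0L || anyNA(shape)) shape <- integer(0)
  dt <- npy_dtypes[[descr]]
  if (is.null(dt)) stopf("unsupported NPY dtype '%s' in %s", descr, path)
  n <- if (length(shape)) prod(shape) else 1L
  if (dt$what == "double") {
    x <- readBin(con, "double", n, size = dt$size, endian = "little")
  } else if (identical(descr, "<i8")) {
    raw8 <- readBin(con, "raw", n * 8L)
    lo <- readBin(raw8[rep(seq_len(n) * 8L - 7L, each = 4L) + 0:3],
                  "integer", n, size = 4L, endian = "little")
    hi <- readBin(raw8[rep(seq_len(n) * 8L - 3L, each = 4L) + 0:3],
                  "integer", n, size = 4L, endian = "little")
    x <- hi * 2^32 + ifelse(lo < 0, lo + 2^32, lo)
  } else if (identical(descr, "<u4")) {
    x <- readBin(con, "integer", n, size = 4L, endian = "little")
    x <- ifelse(x < 0, x + 2^32, as.numeric(x))
  } else {
    x <- readBin(con, "integer", n, size = dt$size, signed = dt$signed,
                 endian = "little")
  }
  if (length(shape) > 1L) {
    if (fortran) {
      dim(x) <- shape
    } else {
      dim(x) <- rev(shape)
      x <- aperm(x, rev(seq_along(shape)))
    }
  }
  x
}

#' Write a numpy array file
#'
#' Writes an R numeric or integer array as `.npy` (format 1.0, C order),
#' readable by numpy and by [read_npy()].
#'
#' @param x numeric or integer vector/array.
#' @param path output path.
#' @param dtype one of `"int32"`, `"float64"`, `"uint8"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path, dtype = if (is.integer(x)) "int32" else "float64") {
  descr <- switch(dtype,
    int32 = "<i4", float64 = "<f8", uint8 = "|u1", int16 = "<i2",
    stopf("unsupported dtype '%s'", dtype))
  size <- switch(dtype, int32 = 4L, float64 = 8L, uint8 = 1L, int16 = 2L)
  shp <- dim(x) %||% length(x)
  shape_txt <- if (length(shp) == 1L) sprintf("(%d,)", shp) else
    sprintf("(%s)", paste(shp, collapse = ", "))
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape_txt)
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  if (!is.null(dim(x))) x <- aperm(x, rev(seq_along(dim(x))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  if (descr == "<f8") {
    writeBin(as.double(x), con, size = 8L, endian = "little")
  } else {
    writeBin(as.integer(x), con, size = size, endian = "little")
  }
  invisible(path)
}

#' Read an NRRD volume
#'
#' Minimal NRRD reader for annotation/template volumes: attached data, `raw`
#' or `gzip` encoding, little-endian scalar types, up to 3 dimensions. NRRD
#' stores data with the fastest axis first; the result is returned with
#' `sizes` as the R array dimension in that same axis order.
#'
#' @param path path to a `.nrrd` file.
#' @return numeric/integer array.
#' @export
read_nrrd <- function(path) {
  assert_file_exists(path, "NRRD file")
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, 1L)
  if (!grepl("^NRRD", first)) stopf("not an NRRD file: %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, 1L)
    if (length(line) == 0L || !nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*")[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  type <- tolower(fields$type)
  enc <- tolower(fields$encoding %||% "raw")
  spec <- switch(type,
    "uchar" = , "uint8" = , "uint8_t" = list(what = "integer", size = 1L, signed = FALSE),
    "short" = , "int16" = , "int16_t" = list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "uint16" = , "uint16_t" = list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "int32" = , "int32_t" = list(what = "integer", size = 4L, signed = TRUE),
    "uint" = , "uint32" = , "uint32_t" = list(what = "uint32", size = 4L, signed = TRUE),
    "float" = list(what = "double", size = 4L, signed = TRUE),
    "double" = list(what = "double", size = 8L, signed = TRUE),
    stopf("unsupported NRRD type '%s'", type))
  n <- prod(sizes)
  payload <- readBin(con, "raw", file.info(path)$size)
  if (enc == "gzip" || enc == "gz") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stopf("unsupported NRRD encoding '%s'", enc)
  }
  x <- if (spec$what == "double") {
    readBin(payload, "double", n, size = spec$size, endian = "little")
  } else if (spec$what == "uint32") {
    v <- readBin(payload, "integer", n, size = 4L, endian = "little")
    ifelse(v < 0, v + 2^32, as.numeric(v))
  } else {
    readBin(payload, "integer", n, size = spec$size, signed = spec$signed,
            endian = "little")
  }
  if (length(sizes) > 1L) dim(x) <- sizes
  x
}
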