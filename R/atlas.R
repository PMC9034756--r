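#' Atlas bundles
#'
#' An atlas bundle ties together one atlas variant's 3D annotation volume,
#' optional grayscale template, voxel size and structure tree. The
#' annotation volume is an integer array in fixed internal axis order
#' AP x DV x ML (anterior->posterior, superior->inferior, left->right);
#' loaders reorder any declared input axis order to this. Voxel indices are
#' exposed 0-based throughout, following the Common Coordinate Framework
#' convention.
#'
#' @name atlas_bundle
NULL

OUTSIDE_ID <- 0L

outside_node <- function() {
  tibble(id = OUTSIDE_ID, acronym = "outside",
         name = "outside brain", parent_id = NA_integer_)
}

new_atlas_bundle <- function(annotation, structure_tree, variant,
                             voxel_size_um = 10, template = NULL,
                             bregma_voxel = c(540, 0, 570)) {
  if (length(dim(annotation)) != 3L) stopf("annotation must be a 3D array")
  if (!is.null(template) && !identical(dim(template), dim(annotation))) {
    stopf("template shape %s differs from annotation shape %s",
          paste(dim(template), collapse = "x"),
          paste(dim(annotation), collapse = "x"))
  }
  if (!is_scalar_number(voxel_size_um) || voxel_size_um <= 0) {
    stopf("voxel_size_um must be a positive scalar")
  }
  if (any(annotation != round(annotation))) stopf("annotation labels must be integers")
  structure_tree <- validate_structure_tree(structure_tree)
  labs <- sort(unique(as.vector(annotation)))
  labs <- labs[labs != 0]
  missing <- setdiff(labs, structure_tree$id)
  if (length(missing)) {
    stopf("annotation labels missing from structure tree: %s",
          paste(missing, collapse = ", "), class = "histoslice_tree_error")
  }
  structure(list(
    variant = match.arg(variant, c("allen", "chon")),
    annotation = annotation,
    template = template,
    voxel_size_um = voxel_size_um,
    bregma_voxel = as.numeric(bregma_voxel),
    structure_tree = structure_tree
  ), class = "atlas_bundle")
}

validate_structure_tree <- function(tree) {
  tree <- as_tibble(tree)
  if (!nrow(tree)) {
    return(tibble(id = integer(), acronym = character(),
                  name = character(), parent_id = integer()))
  }
  need <- c("id", "acronym", "name", "parent_id")
  if (!all(need %in% names(tree))) {
    stopf("structure tree needs columns %s", paste(need, collapse = ", "))
  }
  tree <- tree |>
    mutate(id = as.integer(.data$id), parent_id = as.integer(.data$parent_id),
           acronym = as.character(.data$acronym), name = as.character(.data$name))
  if (anyDuplicated(tree$id)) stopf("structure tree ids are not unique")
  if (any(tree$id <= 0, na.rm = TRUE)) stopf("structure ids must be positive")
  # every parent chain must reach a root without cycles
  parent <- setNames(tree$parent_id, tree$id)
  for (start in tree$id) {
    seen <- integer(); cur <- start
    while (!is.na(cur)) {
      if (cur %in% seen) stopf("cycle in structure tree at id %d", start)
      seen <- c(seen, cur)
      cur <- if (as.character(cur) %in% names(parent)) parent[[as.character(cur)]] else NA_integer_
    }
  }
  tree[need]
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle '%s': %s voxels @ %g um, %d structures>\n",
              x$variant, paste(dim(x$annotation), collapse = "x"),
              x$voxel_size_um, nrow(x$structure_tree)))
  invisible(x)
}

#' Load an annotation volume and structure tree
#'
#' Reads a 3D integer annotation volume (`.npy` or `.nrrd`) and its
#' structure tree (CSV with columns `id,acronym,name,parent_id`, or JSON as
#' an array of objects with those keys), validates that every nonzero label
#' has a tree entry, and returns an [atlas_bundle]. The real Allen 10-um
#' 2017 annotation (1320 x 800 x 1140 in AP x DV x ML order) and the Chon
#' (modified Franklin-Paxinos) labels on the same grid are both handled this
#' way; tests run entirely on generated toy volumes.
#'
#' @param annotation_path volume file (`.npy` / `.nrrd`).
#' @param tree_path structure tree file (`.csv` / `.json`).
#' @param variant `"allen"` or `"chon"`.
#' @param voxel_size_um voxel edge in microns (default 10).
#' @param axis_order character permutation of `c("ap","dv","ml")` describing
#'   the file's axis order; the volume is rearranged to AP x DV x ML.
#' @param template_path optional grayscale template volume, same shape.
#' @param bregma_voxel 0-based voxel index of bregma, `c(ap, dv, ml)`.
#' @return an `atlas_bundle`.
#' @export
load_atlas <- function(annotation_path, tree_path, variant = c("allen", "chon"),
                       voxel_size_um = 10, axis_order = c("ap", "dv", "ml"),
                       template_path = NULL, bregma_voxel = c(540, 0, 570)) {
  variant <- match.arg(variant)
  assert_file_exists(annotation_path, "annotation volume")
  assert_file_exists(tree_path, "structure tree")
  read_vol <- function(p) {
    x <- if (grepl("\\.npy$", p, ignore.case = TRUE)) read_npy(p) else
         if (grepl("\\.nrrd$", p, ignore.case = TRUE)) read_nrrd(p) else
         stopf("volume must be .npy or .nrrd: %s", p)
    if (length(dim(x)) != 3L) stopf("volume in %s is not 3D", p)
    perm <- match(c("ap", "dv", "ml"), axis_order)
    if (anyNA(perm)) stopf("axis_order must be a permutation of ap, dv, ml")
    aperm(x, perm)
  }
  ann <- read_vol(annotation_path)
  tpl <- if (!is.null(template_path)) read_vol(template_path)
  tree <- read_structure_tree(tree_path)
  new_atlas_bundle(ann, tree, variant, voxel_size_um,
                   template = tpl, bregma_voxel = bregma_voxel)
}

read_structure_tree <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    tree <- as_tibble(rec)
  } else {
    tree <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(tree) && !"parent_id" %in% names(tree)) {
    tree <- if ("parent" %in% names(tree)) rename(tree, parent_id = "parent")
            else mutate(tree, parent_id = NA_integer_)
  }
  if (nrow(tree) && is.data.frame(tree$parent_id)) {
    # JSON records with all-null parents come back as an empty data frame
    tree$parent_id <- NA_integer_
  } else if (nrow(tree) && is.list(tree$parent_id)) {
    # mixed null / numeric parents come back as a list column
    tree$parent_id <- vapply(tree$parent_id,
                             function(p) if (is.null(p) || !length(p))
                               NA_integer_ else as.integer(p), integer(1))
  }
  if (nrow(tree)) tree$parent_id[tree$parent_id %in% c(-1, 0)] <- NA_integer_
  tree
}

#' Slice-plane specification
#'
#' Describes where a virtual atlas section lies: viewing plane, signed
#' bregma-relative position in millimetres, and dorsoventral / mediolateral
#' tilt in degrees. The sign conventions are:
#'
#' | plane      | normal axis | positive `position_mm`       |
#' |------------|-------------|------------------------------|
#' | coronal    | AP          | anterior to bregma           |
#' | sagittal   | ML          | animal's right of midline    |
#' | transverse | DV          | ventral to bregma (deeper)   |
#'
#' Positive `ml_tilt_deg` moves the sampled plane anterior (toward lower
#' normal-axis index) on increasing column; positive `dv_tilt_deg` does the
#' same on increasing row. Tilts are capped at 45 degrees; pixels whose
#' tilted sampling coordinate leaves the volume take the background label 0.
#'
#' @param plane `"coronal"`, `"sagittal"` or `"transverse"`.
#' @param position_mm signed bregma-relative position (mm).
#' @param dv_tilt_deg,ml_tilt_deg signed tilt angles (degrees), `|tilt| < 45`.
#' @return a `slice_plane` object.
#' @export
slice_plane <- function(plane = c("coronal", "sagittal", "transverse"),
                        position_mm = 0, dv_tilt_deg = 0, ml_tilt_deg = 0) {
  plane <- match.arg(plane)
  if (abs(dv_tilt_deg) >= 45 || abs(ml_tilt_deg) >= 45) {
    stopf("tilt angles must satisfy |tilt| < 45 degrees")
  }
  structure(list(plane = plane, position_mm = as.numeric(position_mm),
                 dv_tilt_deg = as.numeric(dv_tilt_deg),
                 ml_tilt_deg = as.numeric(ml_tilt_deg)),
            class = "slice_plane")
}

#' @export
print.slice_plane <- function(x, ...) {
  cat(sprintf("<slice_plane %s @ %+.2f mm, DV tilt %+.1f deg, ML tilt %+.1f deg>\n",
              x$plane, x$position_mm, x$dv_tilt_deg, x$ml_tilt_deg))
  invisible(x)
}

plane_axes <- function(plane) {
  switch(plane,
    coronal    = list(normal = 1L, row = 2L, col = 3L),  # rows DV, cols ML
    sagittal   = list(normal = 3L, row = 2L, col = 1L),  # rows DV, cols AP
    transverse = list(normal = 2L, row = 1L, col = 3L))  # rows AP, cols ML
}

plane_sign <- function(plane) {
  # sign s such that index = bregma + s * mm * 1000 / voxel
  switch(plane, coronal = -1, sagittal = +1, transverse = +1)
}

#' Convert a bregma-relative position to a voxel index (and back)
#'
#' `mm_to_index()` maps a signed bregma-relative position (mm) along a
#' plane's normal axis to a fractional 0-based voxel index:
#' `index = bregma_component + sign(plane) * position_mm * 1000 / voxel_size_um`,
#' with sign -1 for coronal (anterior positive) and +1 for sagittal and
#' transverse (see [slice_plane] for the sign table). `index_to_mm()` is the
#' exact inverse.
#'
#' @param bundle an [atlas_bundle].
#' @param position_mm signed position (mm).
#' @param plane plane name.
#' @param index fractional 0-based voxel index along the normal axis.
#' @return fractional voxel index (or mm for `index_to_mm`).
#' @export
mm_to_index <- function(bundle, position_mm,
                        plane = c("coronal", "sagittal", "transverse")) {
  plane <- match.arg(plane)
  ax <- plane_axes(plane)$normal
  idx <- bundle$bregma_voxel[ax] +
    plane_sign(plane) * position_mm * 1000 / bundle$voxel_size_um
  n <- dim(bundle$annotation)[ax]
  if (any(idx < 0 | idx > n - 1)) {
    stopf("position %+g mm maps to voxel index %g, outside [0, %d) along the %s normal axis",
          position_mm[which(idx < 0 | idx > n - 1)[1]],
          idx[which(idx < 0 | idx > n - 1)[1]], n, plane,
          class = "histoslice_out_of_volume")
  }
  idx
}

#' @rdname mm_to_index
#' @export
index_to_mm <- function(bundle, index,
                        plane = c("coronal", "sagittal", "transverse")) {
  plane <- match.arg(plane)
  ax <- plane_axes(plane)$normal
  (index - bundle$bregma_voxel[ax]) * bundle$voxel_size_um /
    (1000 * plane_sign(plane))
}

#' Canvas shape for a viewing plane
#'
#' The registration canvas for a plane is the volume's face for that plane
#' (rows x cols). For the Allen 10-um volume (1320 x 800 x 1140) the coronal
#' canvas is 800 x 1140 pixels, the padding target used during ingest.
#'
#' @inheritParams mm_to_index
#' @return integer `c(rows, cols)`.
#' @export
canvas_shape <- function(bundle, plane = c("coronal", "sagittal", "transverse")) {
  plane <- match.arg(plane)
  ax <- plane_axes(plane)
  dim(bundle$annotation)[c(ax$row, ax$col)]
}

#' Extract an oblique virtual section from an annotation volume
#'
#' Samples the annotation volume on the plane described by `sp`. For pixel
#' (r, c) of the canvas the normal-axis coordinate is
#' `base + tan(ml_tilt) * (c - c_center) + tan(dv_tilt) * (r - r_center)`
#' where `base = mm_to_index(bundle, sp$position_mm, sp$plane)`; labels are
#' sampled nearest-neighbour (labels are categorical ids, interpolation
#' would fabricate them). With both tilts zero the result is bit-identical
#' to direct array slicing at the rounded base index.
#'
#' @param bundle an [atlas_bundle].
#' @param sp a [slice_plane].
#' @return list with `labels` (integer matrix, canvas shape; out-of-volume
#'   pixels are 0) and `coord_map` (canvas x 3 integer array of 0-based
#'   AP/DV/ML voxel indices each pixel was sampled from; `NA` marks the
#'   out-of-volume sentinel).
#' @export
extract_slice <- function(bundle, sp) {
  stopifnot(inherits(sp, "slice_plane"))
  ax <- plane_axes(sp$plane)
  dims <- dim(bundle$annotation)
  base <- mm_to_index(bundle, sp$position_mm, sp$plane)
  nr <- dims[ax$row]; nc <- dims[ax$col]
  r0 <- seq_len(nr) - 1; c0 <- seq_len(nc) - 1
  rc <- (nr - 1) / 2; cc <- (nc - 1) / 2
  ncoord <- base +
    outer(tanpi(sp$dv_tilt_deg / 180) * (r0 - rc),
          tanpi(sp$ml_tilt_deg / 180) * (c0 - cc), "+")
  nidx <- round_half_up(ncoord)
  valid <- in_bounds0(nidx, dims[ax$normal])
  # assemble 0-based AP/DV/ML coordinates per pixel
  coord <- array(NA_integer_, c(nr, nc, 3L))
  coord[, , ax$normal] <- as.integer(nidx)
  coord[, , ax$row] <- matrix(rep(as.integer(r0), nc), nr, nc)
  coord[, , ax$col] <- matrix(rep(as.integer(c0), each = nr), nr, nc)
  coord[, , ax$normal][!valid] <- NA_integer_
  labels <- matrix(0L, nr, nc)
  if (any(valid)) {
    lin <- 1 + coord[, , 1][valid] +
      dims[1] * (coord[, , 2][valid] + dims[2] * coord[, , 3][valid])
    labels[valid] <- as.integer(bundle$annotation[lin])
  }
  coord[, , ax$row][!valid] <- NA_integer_
  coord[, , ax$col][!valid] <- NA_integer_
  list(labels = labels, coord_map = coord)
}

#' Resolve voxel coordinates to brain structures
#'
#' Total function from 0-based voxel coordinates to structure records:
#' out-of-volume coordinates (including `NA` sentinels) and background label
#' 0 both resolve to the reserved "outside brain" record, which participates
#' in tallies like any structure.
#'
#' @param bundle an [atlas_bundle].
#' @param voxel numeric vector `c(ap, dv, ml)` or an n x 3 matrix of 0-based
#'   voxel coordinates.
#' @return tibble with one row per coordinate: `id`, `acronym`, `name`.
#' @export
lookup_region <- function(bundle, voxel) {
  v <- if (is.matrix(voxel)) voxel else matrix(voxel, ncol = 3, byrow = FALSE)
  if (!is.matrix(voxel)) v <- matrix(as.numeric(voxel), ncol = 3)
  dims <- dim(bundle$annotation)
  v <- round_half_up(v)
  ok <- in_bounds0(v[, 1], dims[1]) & in_bounds0(v[, 2], dims[2]) &
        in_bounds0(v[, 3], dims[3])
  ids <- rep(OUTSIDE_ID, nrow(v))
  if (any(ok)) {
    lin <- 1 + v[ok, 1] + dims[1] * (v[ok, 2] + dims[2] * v[ok, 3])
    ids[ok] <- as.integer(bundle$annotation[lin])
  }
  nodes_for_ids(bundle, ids)
}

nodes_for_ids <- function(bundle, ids) {
  tab <- bind_rows(outside_node(), bundle$structure_tree[c("id", "acronym", "name", "parent_id")])
  tibble(id = as.integer(ids)) |>
    left_join(tab[c("id", "acronym", "name")], by = "id")
}
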