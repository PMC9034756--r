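#' Assign warped cell points to brain structures
#'
#' Each atlas-frame point is committed to a canvas pixel (coordinates
#' rounded half-up — region borders below atlas resolution are not
#' meaningful), that pixel's 3D voxel is read off the slice's coordinate
#' map from [extract_slice()], and the voxel is resolved to a structure via
#' [lookup_region()]. Points whose pixel falls off the canvas, samples
#' outside the volume, or lands on background are assigned the
#' "outside brain" record — a first-class category, not an error, since
#' warped points legitimately fall outside the annotation.
#'
#' Quantifying a sagittal slice under the Chon (modified Franklin-Paxinos)
#' labels is rejected: those labels only support coronal and transverse
#' quantification.
#'
#' @param ps `point_set` in the `atlas` frame.
#' @param bundle an [atlas_bundle].
#' @param sp the [slice_plane] the slice was registered to.
#' @param slice_id identifier for the slice (default the point set's
#'   source image).
#' @param transform_path optional provenance path of the transform used.
#' @return a `slice_record`: list with `slice_id`, `slice_plane`,
#'   `atlas_variant`, `points`, `assignments` (tibble `id, acronym, name`,
#'   one row per point) and `transform_path`.
#' @export
assign_regions <- function(ps, bundle, sp, slice_id = NULL,
                           transform_path = NA_character_) {
  assert_frame(ps, "atlas", "assign_regions")
  if (identical(bundle$variant, "chon") && identical(sp$plane, "sagittal")) {
    stopf(paste("sagittal slices cannot be quantified under the Chon atlas;",
                "use the Allen variant or a coronal/transverse plane"),
          class = "histoslice_chon_sagittal")
  }
  slc <- extract_slice(bundle, sp)
  new_slice_record(ps, bundle, sp, slc$coord_map,
                   slice_id %||% attr(ps, "source_image"), transform_path)
}

new_slice_record <- function(ps, bundle, sp, coord_map, slice_id,
                             transform_path = NA_character_) {
  dims <- dim(coord_map)
  vox <- matrix(NA_integer_, nrow(ps), 3)
  if (nrow(ps)) {
    r <- round_half_up(ps$y); c <- round_half_up(ps$x)
    on_canvas <- in_bounds0(r, dims[1]) & in_bounds0(c, dims[2])
    i <- which(on_canvas)
    if (length(i)) {
      pix <- cbind(r[i] + 1L, c[i] + 1L)
      vox[i, ] <- cbind(coord_map[cbind(pix, 1L)],
                        coord_map[cbind(pix, 2L)],
                        coord_map[cbind(pix, 3L)])
    }
  }
  assignments <- lookup_region_voxels(bundle, vox)
  structure(list(slice_id = slice_id, slice_plane = sp,
                 atlas_variant = bundle$variant,
                 points = ps, assignments = assignments,
                 voxels = vox, transform_path = transform_path),
            class = "slice_record")
}

# lookup_region over an n x 3 matrix that may contain NA sentinel rows
lookup_region_voxels <- function(bundle, vox) {
  if (!nrow(vox)) return(nodes_for_ids(bundle, integer()))
  sentinel <- apply(vox, 1, anyNA)
  vox2 <- vox
  vox2[sentinel, ] <- -1  # guaranteed out of volume -> outside record
  lookup_region(bundle, vox2)
}

#' @export
print.slice_record <- function(x, ...) {
  cat(sprintf("<slice_record '%s' (%s, %s): %d points, %d inside brain>\n",
              x$slice_id %||% "?", x$atlas_variant, x$slice_plane$plane,
              nrow(x$points), sum(x$assignments$id != OUTSIDE_ID)))
  invisible(x)
}

#' Point-editing primitives
#'
#' Constructors for the curation edits applied by [edit_points()]: add a
#' point, move or delete one by index (1-based row index), or select a
#' group by drawing a polygon and delete or translate it. Polygon
#' membership uses the even-odd rule and includes boundary points;
#' self-intersecting polygons are rejected.
#'
#' @param x,y coordinates (atlas-frame pixels).
#' @param i point index.
#' @param vertices n x 2 matrix of polygon vertices (x, y), n >= 3.
#' @param action `"delete"` or `"translate"` for the selected group.
#' @param dx,dy translation offsets for `action = "translate"`.
#' @return an edit description for [edit_points()].
#' @name point_edits
NULL

#' @rdname point_edits
#' @export
edit_add <- function(x, y) list(op = "add", x = x, y = y)

#' @rdname point_edits
#' @export
edit_move <- function(i, x, y) list(op = "move", i = i, x = x, y = y)

#' @rdname point_edits
#' @export
edit_delete <- function(i) list(op = "delete", i = i)

#' @rdname point_edits
#' @export
edit_polygon <- function(vertices, action = c("delete", "translate"),
                         dx = 0, dy = 0) {
  action <- match.arg(action)
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stopf("polygon needs at least 3 vertices")
  if (polygon_self_intersects(v)) {
    stopf("self-intersecting polygon rejected", class = "histoslice_polygon")
  }
  list(op = "polygon", vertices = v, action = action, dx = dx, dy = dy)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(v[i, ], v[i %% n + 1, ], v[j, ], v[j %% n + 1, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Even-odd point-in-polygon, boundary inclusive.
points_in_polygon <- function(x, y, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    j <- i %% n + 1
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    cross <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
    # boundary: collinear and within bounding box of the edge
    col <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)) < 1e-9 &
      x >= pmin(x1, x2) - 1e-9 & x <= pmax(x1, x2) + 1e-9 &
      y >= pmin(y1, y2) - 1e-9 & y <= pmax(y1, y2) + 1e-9
    on_edge <- on_edge | col
  }
  inside | on_edge
}

#' Apply curation edits to points
#'
#' Applies a list of edits (see [point_edits]) in order to a `point_set`,
#' or to a `slice_record` — in which case region assignments are recomputed
#' afterwards against the same atlas bundle. Every edit is appended to the
#' point set's edit log (operation, arguments, number of points affected,
#' timestamp) for provenance.
#'
#' @param x a `point_set` or `slice_record`.
#' @param edits list of edits from [edit_add()], [edit_move()],
#'   [edit_delete()], [edit_polygon()].
#' @param bundle atlas bundle, required when `x` is a `slice_record`.
#' @return object of the same class as `x`, updated.
#' @export
edit_points <- function(x, edits, bundle = NULL) {
  if (inherits(x, "slice_record")) {
    if (is.null(bundle)) stopf("editing a slice_record requires its atlas bundle")
    ps <- edit_points(x$points, edits)
    return(assign_regions(ps, bundle, x$slice_plane, slice_id = x$slice_id,
                          transform_path = x$transform_path))
  }
  ps <- x
  if (!is.null(edits$op)) edits <- list(edits)
  log <- attr(ps, "edit_log") %||%
    tibble(op = character(), detail = character(), n_affected = integer(),
           time = as.POSIXct(character()))
  df <- as_tibble(ps)
  for (e in edits) {
    n_aff <- 1L
    if (e$op == "add") {
      new_row <- df[0, ]
      new_row[1, c("x", "y")] <- list(e$x, e$y)
      df <- bind_rows(df, new_row)
      detail <- sprintf("(%g, %g)", e$x, e$y)
    } else if (e$op == "move") {
      if (e$i < 1 || e$i > nrow(df)) stopf("edit index %d out of range [1, %d]",
                                           e$i, nrow(df))
      df$x[e$i] <- e$x; df$y[e$i] <- e$y
      detail <- sprintf("#%d -> (%g, %g)", e$i, e$x, e$y)
    } else if (e$op == "delete") {
      if (e$i < 1 || e$i > nrow(df)) stopf("edit index %d out of range [1, %d]",
                                           e$i, nrow(df))
      df <- df[-e$i, ]
      detail <- sprintf("#%d", e$i)
    } else if (e$op == "polygon") {
      sel <- points_in_polygon(df$x, df$y, e$vertices)
      n_aff <- sum(sel)
      if (e$action == "delete") {
        df <- df[!sel, ]
      } else {
        df$x[sel] <- df$x[sel] + e$dx
        df$y[sel] <- df$y[sel] + e$dy
      }
      detail <- sprintf("%s %d point(s) in %d-gon", e$action, n_aff,
                        nrow(e$vertices))
    } else {
      stopf("unknown edit op '%s'", e$op)
    }
    log <- bind_rows(log, tibble(op = e$op, detail = detail,
                                 n_affected = as.integer(n_aff),
                                 time = Sys.time()))
  }
  new_point_set(df, frame = point_frame(ps),
                source_image = attr(ps, "source_image"), edit_log = log)
}

#' Tally cell counts by brain region
#'
#' Builds the region-count table: per slice, or aggregated per brain
#' (element-wise sum across slices). The "outside brain" category is a row
#' like any other, so the table total always equals the number of input
#' cell points — counts are conserved end-to-end from coordinate-file
#' ingest. Counts are reported at the annotation's leaf label; set
#' `rollup = TRUE` to add each count to all its ancestors as extra rows.
#'
#' @param records a `slice_record` or list of them (all under the same
#'   atlas variant).
#' @param scope `"per_brain"` (default) or `"per_slice"`.
#' @param rollup also accumulate counts into ancestor structures.
#' @param tree structure tree tibble (`id, acronym, name, parent_id`),
#'   required when `rollup = TRUE`.
#' @return a `region_count_table` tibble: `structure id, acronym, name,
#'   count` (plus `slice_id` for per-slice scope), with attributes
#'   `scope`, `atlas_variant`, `total`.
#' @export
tally_regions <- function(records, scope = c("per_brain", "per_slice"),
                          rollup = FALSE, tree = NULL) {
  scope <- match.arg(scope)
  if (inherits(records, "slice_record")) records <- list(records)
  variants <- unique(map_chr(records, "atlas_variant"))
  if (length(variants) > 1L) {
    stopf("cannot tally records from mixed atlas variants: %s",
          paste(variants, collapse = ", "), class = "histoslice_mixed_variants")
  }
  if (!length(records)) {
    empty <- tibble(id = integer(), acronym = character(),
                    name = character(), count = integer())
    if (scope == "per_slice") empty <- mutate(empty, slice_id = character(),
                                              .before = 1)
    return(structure(empty, scope = scope, atlas_variant = NA_character_,
                     total = 0L,
                     class = c("region_count_table", class(empty))))
  }
  per_slice <- map(records, function(r) {
    r$assignments |>
      mutate(slice_id = r$slice_id %||% NA_character_) |>
      count(.data$slice_id, .data$id, .data$acronym, .data$name, name = "count")
  }) |> bind_rows()
  tab <- if (scope == "per_slice") per_slice else
    per_slice |>
      group_by(.data$id, .data$acronym, .data$name) |>
      summarise(count = sum(.data$count), .groups = "drop")
  if (rollup && nrow(tab)) {
    if (is.null(tree)) stopf("rollup requires the structure tree (tree =)")
    tab <- rollup_counts(tab, tree, scope)
  }
  tab <- arrange(tab, dplyr::desc(.data$count), .data$id)
  structure(tab, scope = scope,
            atlas_variant = if (length(variants)) variants else NA_character_,
            total = sum(tab$count),
            class = c("region_count_table", class(tab)))
}

rollup_counts <- function(tab, tree, scope) {
  parent <- setNames(tree$parent_id, tree$id)
  lift <- function(df) {
    extra <- df
    out <- df
    repeat {
      extra <- extra |>
        filter(.data$id %in% as.integer(names(parent))) |>
        mutate(id = unname(parent[as.character(.data$id)])) |>
        filter(!is.na(.data$id))
      if (!nrow(extra)) break
      out <- bind_rows(out, extra |> select(-any_of(c("acronym", "name"))) |>
                         left_join(tree[c("id", "acronym", "name")], by = "id"))
    }
    grp <- intersect(c("slice_id", "id", "acronym", "name"), names(out))
    out |> group_by(across(all_of(grp))) |>
      summarise(count = sum(.data$count), .groups = "drop")
  }
  lift(tab)
}

#' @export
print.region_count_table <- function(x, ...) {
  cat(sprintf("<region_count_table (%s, %s): %d rows, total %d cells>\n",
              attr(x, "atlas_variant"), attr(x, "scope"), nrow(x),
              attr(x, "total")))
  NextMethod()
}

#' Lift a slice record into 3D atlas space
#'
#' Converts each point's sampled voxel (from the slice's coordinate map) to
#' micron coordinates in the atlas space, `voxel index x voxel size`.
#' Outside-brain points carry `NA` coordinates on the sampled axes but are
#' exported with their `outside` flag set rather than dropped.
#'
#' @param record a `slice_record`.
#' @param bundle the [atlas_bundle] used for assignment.
#' @return tibble: `ap_um, dv_um, ml_um, structure_id, acronym, name,
#'   slice_id, outside`.
#' @export
to_ccf3d <- function(record, bundle) {
  v <- record$voxels
  vs <- bundle$voxel_size_um
  tibble(ap_um = v[, 1] * vs, dv_um = v[, 2] * vs, ml_um = v[, 3] * vs,
         structure_id = record$assignments$id,
         acronym = record$assignments$acronym,
         name = record$assignments$name,
         slice_id = record$slice_id %||% NA_character_,
         outside = record$assignments$id == OUTSIDE_ID)
}

#' Compare quantification under two atlas ontologies
#'
#' Given per-slice region-count tables for the same cells under the Allen
#' and Chon ontologies, computes: the Pearson correlation of paired
#' per-slice cell totals (count fidelity between atlases), a paired t test
#' on the number of distinct structures hit per slice (delineation
#' granularity), and the number of structure names shared verbatim between
#' the two tables (exact-name nomenclature overlap).
#'
#' @param table_allen,table_chon per-slice `region_count_table`s covering
#'   the same slices (>= 3 paired slices).
#' @return one-row tibble: `n_slices, pearson_r, t_stat, df, p_value,
#'   mean_structures_allen, sd_structures_allen, mean_structures_chon,
#'   sd_structures_chon, name_overlap`.
#' @export
compare_atlases <- function(table_allen, table_chon) {
  per_slice <- function(tab) {
    as_tibble(tab) |>
      group_by(.data$slice_id) |>
      summarise(total = sum(.data$count),
                n_structures = n_distinct(.data$id[.data$id != OUTSIDE_ID]),
                .groups = "drop")
  }
  a <- per_slice(table_allen); b <- per_slice(table_chon)
  if (!setequal(a$slice_id, b$slice_id) || nrow(a) != nrow(b)) {
    stopf("the two tables cover different slices")
  }
  m <- inner_join(a, b, by = "slice_id", suffix = c("_allen", "_chon"))
  if (nrow(m) < 3L) {
    stopf("atlas comparison needs at least 3 paired slices, got %d", nrow(m),
          class = "histoslice_insufficient_n")
  }
  r <- cor(m$total_allen, m$total_chon)
  d <- m$n_structures_allen - m$n_structures_chon
  tt <- if (sd(d) == 0) {
    # degenerate paired test (all differences equal): t is 0 when the
    # difference is 0, infinite otherwise
    list(statistic = if (all(d == 0)) 0 else sign(mean(d)) * Inf,
         parameter = nrow(m) - 1,
         p.value = if (all(d == 0)) 1 else 0)
  } else {
    t.test(m$n_structures_allen, m$n_structures_chon, paired = TRUE)
  }
  names_a <- setdiff(unique(as_tibble(table_allen)$name), "outside brain")
  names_b <- setdiff(unique(as_tibble(table_chon)$name), "outside brain")
  tibble(n_slices = nrow(m), pearson_r = r,
         t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_structures_allen = mean(m$n_structures_allen),
         sd_structures_allen = sd(m$n_structures_allen),
         mean_structures_chon = mean(m$n_structures_chon),
         sd_structures_chon = sd(m$n_structures_chon),
         name_overlap = length(intersect(names_a, names_b)))
}

#' Write per-slice and per-brain quantification outputs
#'
#' `write_cell_regions()` writes the per-slice region list (one row per
#' cell: slice, coordinates, structure). `write_region_counts()` writes a
#' count table as CSV.
#'
#' @param record a `slice_record`; `tab` a `region_count_table`; `path`
#'   output file.
#' @return `path`, invisibly.
#' @export
write_cell_regions <- function(record, path) {
  out <- tibble(slice_id = record$slice_id %||% NA_character_,
                x = record$points$x, y = record$points$y,
                structure_id = record$assignments$id,
                acronym = record$assignments$acronym,
                name = record$assignments$name)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cell_regions
#' @export
write_region_counts <- function(tab, path) {
  readr::write_csv(as_tibble(tab), path, progress = FALSE)
  invisible(path)
}
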