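#' Region-border map of a label image
#'
#' TRUE wherever a pixel's label differs from any of its 4-neighbours
#' (border thickness 1 px at atlas resolution).
#'
#' @param labels integer label matrix.
#' @return logical matrix of the same shape.
#' @export
border_map <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  edge <- matrix(FALSE, nr, nc)
  if (nr > 1) {
    d <- labels[-1, , drop = FALSE] != labels[-nr, , drop = FALSE]
    edge[-nr, ] <- edge[-nr, ] | d
    edge[-1, ] <- edge[-1, ] | d
  }
  if (nc > 1) {
    d <- labels[, -1, drop = FALSE] != labels[, -nc, drop = FALSE]
    edge[, -nc] <- edge[, -nc] | d
    edge[, -1] <- edge[, -1] | d
  }
  edge
}

#' Overlay specification
#'
#' Controls which layers [composite_overlay()] blends: the warped slice
#' image, the cell markers, and the atlas region borders. At least one
#' layer must be enabled.
#'
#' @param show_image,show_points,show_borders layer switches.
#' @param marker_radius_px cell-marker radius in canvas pixels.
#' @param channel_colors vector of hex colors recycled over image channels.
#' @param point_color,border_color layer colors (hex).
#' @return an `overlay_spec` list.
#' @export
overlay_spec <- function(show_image = TRUE, show_points = TRUE,
                         show_borders = TRUE, marker_radius_px = 2,
                         channel_colors = c("#2040ff", "#30d040", "#e03030"),
                         point_color = "#ffff00", border_color = "#ffffff") {
  if (!show_image && !show_points && !show_borders) {
    stopf("at least one overlay layer must be enabled")
  }
  structure(list(show_image = show_image, show_points = show_points,
                 show_borders = show_borders,
                 marker_radius_px = marker_radius_px,
                 channel_colors = channel_colors, point_color = point_color,
                 border_color = border_color), class = "overlay_spec")
}

hex_to_rgb <- function(hex) as.numeric(grDevices::col2rgb(hex)) / 255

#' Compose the image / cells / atlas-border overlay
#'
#' Deterministically blends up to three layers on the atlas canvas: the
#' warped slice image (each channel tinted with its color, additive),
#' filled disc markers at the warped cell coordinates, and the 1-px region
#' borders of the atlas label image. This is the per-slice composite
#' review image of the pipeline.
#'
#' @param warped_image canvas-shaped matrix or array (x channels) from
#'   [warp_image()], or `NULL` when `show_image` is off.
#' @param record `slice_record` (or `point_set` in the atlas frame)
#'   providing marker positions, or `NULL`.
#' @param labels atlas label matrix from [extract_slice()], or `NULL`.
#' @param spec an [overlay_spec()].
#' @param path optional output TIFF path.
#' @return rows x cols x 3 RGB array in `[0, 1]`; written to `path` if given.
#' @export
composite_overlay <- function(warped_image = NULL, record = NULL,
                              labels = NULL, spec = overlay_spec(),
                              path = NULL) {
  shapes <- list()
  if (!is.null(warped_image)) shapes$image <- dim(warped_image)[1:2]
  if (!is.null(labels)) shapes$labels <- dim(labels)
  if (!length(shapes)) {
    if (is.null(record)) stopf("no layer input given")
    stopf("point-only overlays need an explicit canvas: pass labels or image")
  }
  shp <- shapes[[1]]
  if (!all(vapply(shapes, identical, TRUE, shp))) {
    stopf("overlay layers have mismatched canvas shapes")
  }
  rgb <- array(0, c(shp[1], shp[2], 3))
  if (spec$show_image && !is.null(warped_image)) {
    img <- if (length(dim(warped_image)) == 2L) {
      array(warped_image, c(shp, 1))
    } else warped_image
    for (k in seq_len(dim(img)[3])) {
      ch <- img[, , k] / max(img[, , k], 1)
      col <- hex_to_rgb(spec$channel_colors[(k - 1) %% length(spec$channel_colors) + 1])
      for (c3 in 1:3) rgb[, , c3] <- rgb[, , c3] + ch * col[c3]
    }
  }
  if (spec$show_borders && !is.null(labels)) {
    edge <- border_map(labels)
    col <- hex_to_rgb(spec$border_color)
    for (c3 in 1:3) rgb[, , c3][edge] <- col[c3]
  }
  if (spec$show_points && !is.null(record)) {
    ps <- if (inherits(record, "slice_record")) record$points else record
    if (nrow(ps)) {
      col <- hex_to_rgb(spec$point_color)
      rad <- spec$marker_radius_px
      off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
      off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
      r0 <- round_half_up(ps$y); c0 <- round_half_up(ps$x)
      rr <- rep(r0, each = nrow(off)) + off$dr
      cc <- rep(c0, each = nrow(off)) + off$dc
      keep <- in_bounds0(rr, shp[1]) & in_bounds0(cc, shp[2])
      for (c3 in 1:3) {
        plane <- rgb[, , c3]
        plane[cbind(rr[keep] + 1, cc[keep] + 1)] <- col[c3]
        rgb[, , c3] <- plane
      }
    }
  }
  rgb <- pmin(pmax(rgb, 0), 1)
  if (!is.null(path)) tiff::writeTIFF(rgb, path, bits.per.sample = 8L)
  invisible(rgb)
}

# Boundary voxels of the brain mask (nonzero annotation): mask voxels with
# at least one 6-neighbour outside the mask. Returns an n x 3 matrix of
# 0-based voxel coordinates.
mask_surface_voxels <- function(annotation) {
  m <- annotation != 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    src <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    idx[[ax]] <- if (by > 0) seq_len(n - 1) else 2:n
    src[[ax]] <- if (by > 0) 2:n else seq_len(n - 1)
    shifted <- array(FALSE, d)
    shifted <- do.call(`[<-`, c(list(shifted), idx,
                                list(do.call(`[`, c(list(m), src)))))
    acc & shifted
  }
  for (ax in 1:3) for (by in c(-1, 1)) interior <- shift_and(interior, ax, by)
  surf <- m & !interior
  which(surf, arr.ind = TRUE) - 1L
}

#' Render the whole-brain 3D point cloud
#'
#' Draws the compiled cell cloud inside a brain-outline formed by the
#' surface voxels of the annotation's nonzero mask, as a static figure:
#' three orthographic projections (coronal, sagittal, transverse) side by
#' side. The underlying point table is always written next to the figure
#' as CSV, so the plot is a pure view of exported data.
#'
#' @param clouds a tibble from [to_ccf3d()] or a list of them (rows are
#'   bound together).
#' @param bundle the [atlas_bundle] providing the outline mask.
#' @param path output figure path (`.png`/`.pdf`); the CSV companion is
#'   written with the same stem.
#' @param max_outline_points subsample cap for outline vertices.
#' @return invisibly, a list with the `ggplot` object, the cloud tibble and
#'   the `csv` path.
#' @export
plot_brain_cloud <- function(clouds, bundle, path,
                             max_outline_points = 4000) {
  cloud <- if (is.data.frame(clouds)) as_tibble(clouds) else bind_rows(clouds)
  surf <- mask_surface_voxels(bundle$annotation)
  if (nrow(surf) > max_outline_points) {
    keep <- round(seq(1, nrow(surf), length.out = max_outline_points))
    surf <- surf[keep, , drop = FALSE]
  }
  vs <- bundle$voxel_size_um
  outline <- tibble(ap_um = surf[, 1] * vs, dv_um = surf[, 2] * vs,
                    ml_um = surf[, 3] * vs)
  proj <- function(df, xvar, yvar, panel) {
    tibble(h = df[[xvar]], v = df[[yvar]], panel = panel)
  }
  pts <- filter(cloud, !.data$outside)
  mk <- function(df) bind_rows(
    proj(df, "ml_um", "dv_um", "coronal (ML vs DV)"),
    proj(df, "ap_um", "dv_um", "sagittal (AP vs DV)"),
    proj(df, "ml_um", "ap_um", "transverse (ML vs AP)"))
  g <- ggplot2::ggplot() +
    ggplot2::geom_point(data = mk(outline),
                        ggplot2::aes(x = .data$h, y = .data$v),
                        color = "grey75", size = 0.2, alpha = 0.5) +
    ggplot2::geom_point(data = mk(pts),
                        ggplot2::aes(x = .data$h, y = .data$v),
                        color = "#d02020", size = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(paste(mu, "m")),
                  y = expression(paste(mu, "m")),
                  title = "Whole-brain cell cloud (atlas space)") +
    ggplot2::theme_minimal()
  csv <- paste0(sub("\\.[^.]+$", "", path), ".csv")
  readr::write_csv(cloud, csv, progress = FALSE)
  ggplot2::ggsave(path, g, width = 9, height = 3.2, dpi = 150)
  invisible(list(plot = g, cloud = cloud, csv = csv))
}

#' Plot a region-count table
#'
#' Horizontal bar chart of cell counts per structure (top `max_regions`),
#' outside-brain included.
#'
#' @param object a `region_count_table`.
#' @param max_regions number of structures shown.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot region_count_table
#' @export
autoplot.region_count_table <- function(object, max_regions = 25, ...) {
  df <- as_tibble(object) |>
    group_by(.data$id, .data$acronym, .data$name) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(dplyr::desc(.data$count)) |>
    utils::head(max_regions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count,
                                   y = stats::reorder(.data$acronym, .data$count))) +
    ggplot2::geom_col(fill = "#3060c0") +
    ggplot2::labs(x = "cells", y = NULL,
                  title = sprintf("Cells per region (%s atlas)",
                                  attr(object, "atlas_variant"))) +
    ggplot2::theme_minimal()
}

#' Plot a slice record
#'
#' Scatter of warped cell positions on the atlas canvas, colored by
#' assigned structure, with region borders underneath when a bundle is
#' given.
#'
#' @param object a `slice_record`.
#' @param bundle optional [atlas_bundle] to draw region borders.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot slice_record
#' @export
autoplot.slice_record <- function(object, bundle = NULL, ...) {
  df <- tibble(x = object$points$x, y = object$points$y,
               acronym = object$assignments$acronym)
  g <- ggplot2::ggplot()
  if (!is.null(bundle)) {
    slc <- extract_slice(bundle, object$slice_plane)
    edge <- which(border_map(slc$labels), arr.ind = TRUE)
    if (nrow(edge)) {
      g <- g + ggplot2::geom_point(
        data = tibble(x = edge[, 2] - 1, y = edge[, 1] - 1),
        ggplot2::aes(x = .data$x, y = .data$y),
        color = "grey80", size = 0.1)
    }
  }
  g + ggplot2::geom_point(data = df,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$acronym), size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Slice %s (%s atlas)",
                                  object$slice_id %||% "?",
                                  object$atlas_variant),
                  x = "atlas col (px)", y = "atlas row (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
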