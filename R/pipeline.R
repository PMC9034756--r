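# Batch pipeline over a project directory: the headless counterparts of the
# six interactive steps (pre-process, register to atlas, warp the cell
# coordinates, quantify per slice, aggregate per brain, render the 3D
# cloud), plus `simulate`, which scaffolds a complete synthetic project.
#
# Project layout (paths configurable in project.yaml):
#   images/            <id>.tif            raw slice images
#   roi_coordinates/   <id>.csv            counted-cell coordinates
#   landmarks/         <id>.csv            landmark pairs (padded <-> atlas)
#   processed/                             padded images, transforms, points
#   output/<variant>/                      per-slice and per-brain results
# Images, coordinate files and landmark files pair by identical basename.

#' Read and validate a project configuration
#'
#' Loads a YAML project file, resolves directories relative to its
#' location, and validates the image / coordinate-file pairing rule (files
#' pair by identical basename; unpaired files are an error naming the
#' basename).
#'
#' @param path path to `project.yaml`.
#' @return a validated `project_config` list.
#' @export
read_project_config <- function(path) {
  assert_file_exists(path, "project config")
  cfg <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  known <- c("plane", "pixel_size_um", "atlas_voxel_um", "canvas",
             "transform_family", "strict_landmarks", "contrast", "atlases",
             "bregma_voxel", "directories", "slices", "variant", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stopf("invalid config keys: %s", paste(bad, collapse = ", "))
  dirs <- cfg$directories %||% list()
  defaults <- list(images = "images", points = "roi_coordinates",
                   landmarks = "landmarks", processed = "processed",
                   output = "output")
  for (nm in names(defaults)) {
    dirs[[nm]] <- file.path(root, dirs[[nm]] %||% defaults[[nm]])
  }
  for (v in names(cfg$atlases)) {
    for (fld in c("annotation", "tree")) {
      cfg$atlases[[v]][[fld]] <- file.path(root, cfg$atlases[[v]][[fld]])
    }
  }
  cfg$directories <- dirs
  cfg$root <- root
  cfg$plane <- cfg$plane %||% "coronal"
  cfg$atlas_voxel_um <- cfg$atlas_voxel_um %||% 10
  cfg$canvas <- if (identical(cfg$canvas, "auto")) NULL else
    as.integer(cfg$canvas %||% c(800L, 1140L))
  cfg$transform_family <- cfg$transform_family %||% "projective"
  cfg$strict_landmarks <- cfg$strict_landmarks %||% TRUE
  cfg$variant <- cfg$variant %||% names(cfg$atlases)[1]
  # pairing rule: every image must have a coordinate file of the same
  # basename (and vice versa)
  if (dir.exists(dirs$images)) {
    img <- sub("\\.tiff?$", "", list.files(dirs$images, pattern = "\\.tiff?$"))
    pts <- sub("\\.(csv|txt)$", "",
               list.files(dirs$points, pattern = "\\.(csv|txt)$"))
    orphans <- c(setdiff(img, pts), setdiff(pts, img))
    if (length(orphans)) {
      stopf("unpaired image/coordinate files (basenames): %s",
            paste(sort(unique(orphans)), collapse = ", "),
            class = "histoslice_pairing_error")
    }
    cfg$slice_ids <- sort(img)
  } else {
    cfg$slice_ids <- character()
  }
  structure(cfg, class = "project_config")
}

slice_plane_for <- function(cfg, id) {
  for (s in cfg$slices %||% list()) {
    if (identical(s$id, id)) {
      return(slice_plane(cfg$plane, s$position_mm %||% 0,
                         s$dv_tilt_deg %||% 0, s$ml_tilt_deg %||% 0))
    }
  }
  stopf("no slice entry in config for image '%s'", id)
}

load_config_atlas <- function(cfg, variant) {
  a <- cfg$atlases[[variant]]
  if (is.null(a)) stopf("atlas variant '%s' not in config", variant)
  load_atlas(a$annotation, a$tree, variant,
             voxel_size_um = cfg$atlas_voxel_um,
             bregma_voxel = cfg$bregma_voxel %||% c(540, 0, 570))
}

write_manifest <- function(cfg, step, extra = list()) {
  dir.create(cfg$directories$output, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cfg$directories$output, "manifest.json")
  prev <- if (file.exists(path)) jsonlite::fromJSON(path, simplifyVector = FALSE)
          else list()
  prev[[step]] <- c(list(
    package_version = as.character(utils::packageVersion("histoslice")),
    plane = cfg$plane, pixel_size_um = cfg$pixel_size_um,
    atlas_voxel_um = cfg$atlas_voxel_um,
    transform_family = cfg$transform_family,
    strict_landmarks = cfg$strict_landmarks), extra)
  jsonlite::write_json(prev, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a pipeline step over a project directory
#'
#' Executes one batch step headlessly; later steps require the outputs of
#' earlier ones. Steps:
#' * `simulate` — scaffold a complete synthetic project (toy atlases,
#'   rendered slices, coordinate and landmark files, `project.yaml`) under
#'   `config` interpreted as a target directory.
#' * `preprocess` — downsample to atlas resolution, pad to the canvas,
#'   transform points; writes padded TIFFs, point CSVs and canvas records
#'   into `processed/`.
#' * `register` — fit the landmark transform per slice; writes transform
#'   JSONs and composite TIFFs.
#' * `warp_points` — apply each saved transform to the padded points;
#'   writes atlas-frame point CSVs.
#' * `quantify` — assign regions per slice under the selected variant;
#'   writes one cell-region CSV per slice.
#' * `aggregate` — compile the per-brain region-count CSV.
#' * `render3d` — write the whole-brain cloud figure and CSV.
#' * `all` — everything after `simulate`, in order.
#'
#' Re-running a step overwrites its outputs deterministically; parameters
#' are logged to `output/manifest.json`.
#'
#' @param config path to `project.yaml` (or a directory for `simulate`),
#'   or a `project_config`.
#' @param step step name (see above).
#' @param seed integer seed (used by `simulate`).
#' @param variant atlas variant override (default from config).
#' @return paths of the files written, invisibly (for `simulate`, the
#'   config path).
#' @export
run_pipeline <- function(config,
                         step = c("preprocess", "register", "warp_points",
                                  "quantify", "aggregate", "render3d",
                                  "simulate", "all"),
                         seed = NULL, variant = NULL) {
  step <- match.arg(step)
  if (step == "simulate") {
    return(simulate_project(config, seed = seed %||% 1))
  }
  cfg <- if (inherits(config, "project_config")) config
         else read_project_config(config)
  variant <- variant %||% cfg$variant
  if (step == "all") {
    out <- lapply(c("preprocess", "register", "warp_points", "quantify",
                    "aggregate", "render3d"),
                  function(s) run_pipeline(cfg, s, seed = seed, variant = variant))
    return(invisible(unlist(out)))
  }
  dirs <- cfg$directories
  dir.create(dirs$processed, recursive = TRUE, showWarnings = FALSE)
  outv <- file.path(dirs$output, variant)
  dir.create(outv, recursive = TRUE, showWarnings = FALSE)
  p_padded <- function(id) file.path(dirs$processed, paste0(id, "_padded.tif"))
  p_pts <- function(id) file.path(dirs$processed, paste0(id, "_padded_points.csv"))
  p_canvas <- function(id) file.path(dirs$processed, paste0(id, "_canvas.json"))
  p_tf <- function(id) file.path(dirs$processed, paste0(id, "_transform.json"))
  p_atlas_pts <- function(id) file.path(dirs$processed, paste0(id, "_atlas_points.csv"))
  p_regions <- function(id) file.path(outv, paste0(id, "_cell_regions.csv"))
  need <- function(path, from) {
    if (!file.exists(path)) {
      stopf("missing %s (run the '%s' step first)", path, from,
            class = "histoslice_missing_step")
    }
    path
  }
  written <- character()
  if (step == "preprocess") {
    for (id in cfg$slice_ids) {
      img_file <- list.files(dirs$images, pattern = paste0("^", id, "\\.tiff?$"),
                             full.names = TRUE)[1]
      pt_file <- list.files(dirs$points, pattern = paste0("^", id, "\\.(csv|txt)$"),
                            full.names = TRUE)[1]
      raw <- read_slice_image(img_file, cfg$pixel_size_um)
      dialect <- if (grepl("\\.txt$", pt_file)) "photoshop_txt" else "fiji_csv"
      pts <- read_points(pt_file, dialect)
      canvas <- cfg$canvas %||% {
        b <- load_config_atlas(cfg, variant)
        canvas_shape(b, cfg$plane)
      }
      pp <- preprocess(raw, pts, atlas_voxel_um = cfg$atlas_voxel_um,
                       canvas = canvas, contrast = cfg$contrast)
      tiff::writeTIFF(pp$image / max(pp$image, 1), p_padded(id),
                      bits.per.sample = 16L)
      readr::write_csv(as_tibble(pp$points), p_pts(id), progress = FALSE)
      write_canvas_record(pp$canvas_record, p_canvas(id))
      written <- c(written, p_padded(id), p_pts(id), p_canvas(id))
    }
  } else if (step == "register") {
    for (id in cfg$slice_ids) {
      lm_file <- file.path(dirs$landmarks, paste0(id, ".csv"))
      assert_file_exists(lm_file, sprintf("landmark file for slice '%s'", id))
      lms <- read_landmarks(lm_file)
      sp <- slice_plane_for(cfg, id)
      tf <- fit_transform(lms, cfg$transform_family, sp = sp,
                          strict = cfg$strict_landmarks)
      save_transform(tf, p_tf(id))
      written <- c(written, p_tf(id))
      if (file.exists(p_padded(id))) {
        img <- tiff::readTIFF(p_padded(id), as.is = TRUE)
        cshape <- dim(img)[1:2]
        warped <- warp_image(img, tf, cshape)
        comp <- file.path(outv, paste0(id, "_composite.tif"))
        b <- load_config_atlas(cfg, variant)
        slc <- extract_slice(b, sp)
        composite_overlay(warped, NULL, slc$labels,
                          overlay_spec(show_points = FALSE), path = comp)
        written <- c(written, comp)
      }
    }
  } else if (step == "warp_points") {
    for (id in cfg$slice_ids) {
      pts <- readr::read_csv(need(p_pts(id), "preprocess"),
                             show_col_types = FALSE, progress = FALSE)
      ps <- new_point_set(pts, frame = "padded", source_image = id)
      warped <- apply_saved_transform(need(p_tf(id), "register"), ps)
      readr::write_csv(as_tibble(warped), p_atlas_pts(id), progress = FALSE)
      written <- c(written, p_atlas_pts(id))
    }
  } else if (step == "quantify") {
    b <- load_config_atlas(cfg, variant)
    for (id in cfg$slice_ids) {
      pts <- readr::read_csv(need(p_atlas_pts(id), "warp_points"),
                             show_col_types = FALSE, progress = FALSE)
      ps <- new_point_set(pts, frame = "atlas", source_image = id)
      rec <- assign_regions(ps, b, slice_plane_for(cfg, id), slice_id = id,
                            transform_path = p_tf(id))
      write_cell_regions(rec, p_regions(id))
      written <- c(written, p_regions(id))
    }
  } else if (step == "aggregate") {
    b <- load_config_atlas(cfg, variant)
    recs <- lapply(cfg$slice_ids, function(id) {
      pts <- readr::read_csv(need(p_atlas_pts(id), "warp_points"),
                             show_col_types = FALSE, progress = FALSE)
      assign_regions(new_point_set(pts, frame = "atlas", source_image = id),
                     b, slice_plane_for(cfg, id), slice_id = id)
    })
    tab <- tally_regions(recs, "per_brain")
    per_slice <- tally_regions(recs, "per_slice")
    f1 <- file.path(outv, "region_counts.csv")
    f2 <- file.path(outv, "region_counts_per_slice.csv")
    write_region_counts(tab, f1)
    write_region_counts(per_slice, f2)
    written <- c(written, f1, f2)
  } else if (step == "render3d") {
    b <- load_config_atlas(cfg, variant)
    clouds <- lapply(cfg$slice_ids, function(id) {
      pts <- readr::read_csv(need(p_atlas_pts(id), "warp_points"),
                             show_col_types = FALSE, progress = FALSE)
      rec <- assign_regions(new_point_set(pts, frame = "atlas",
                                          source_image = id),
                            b, slice_plane_for(cfg, id), slice_id = id)
      to_ccf3d(rec, b)
    })
    fig <- file.path(outv, "brain_cloud.png")
    res <- plot_brain_cloud(clouds, b, fig)
    written <- c(written, fig, res$csv)
  }
  write_manifest(cfg, step, list(variant = variant,
                                 n_slices = length(cfg$slice_ids)))
  invisible(written)
}

#' Scaffold a synthetic test project
#'
#' Drives the fixture generators to lay out a complete project directory —
#' toy Allen and Chon atlas volumes (NPY) with structure trees (CSV),
#' rendered slice TIFFs, FIJI-dialect coordinate CSVs, landmark CSVs and a
#' `project.yaml` — so the full pipeline can run end to end with no
#' external data. The ground truth for each slice is returned so callers
#' can verify the pipeline output against it.
#'
#' @param dir target project directory (created).
#' @param seed integer seed.
#' @param n_slices number of synthetic slices (default 2).
#' @param cells_per_region named vector, region id -> cells per slice.
#' @return list with `config` (path to `project.yaml`) and `truth` (list of
#'   `fixture_truth`, one per slice).
#' @export
simulate_project <- function(dir, seed = 1, n_slices = 2,
                             cells_per_region = c("2" = 25, "3" = 15, "4" = 10)) {
  for (d in c("images", "roi_coordinates", "landmarks", "atlas")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  allen <- make_toy_atlas(seed, variant = "allen")
  chon <- make_toy_atlas(seed, variant = "chon")
  write_npy(allen$annotation, file.path(dir, "atlas", "allen_annotation.npy"),
            dtype = "int32")
  write_npy(chon$annotation, file.path(dir, "atlas", "chon_annotation.npy"),
            dtype = "int32")
  readr::write_csv(allen$structure_tree, file.path(dir, "atlas", "allen_tree.csv"),
                   progress = FALSE)
  readr::write_csv(chon$structure_tree, file.path(dir, "atlas", "chon_tree.csv"),
                   progress = FALSE)
  positions <- seq(-0.05, 0.05, length.out = n_slices)
  truth <- list()
  slices <- list()
  for (i in seq_len(n_slices)) {
    id <- sprintf("slice%02d", i)
    sp <- slice_plane("coronal", positions[i])
    H <- matrix(c(1.02, 0.015, -1.5,
                  -0.01, 0.985, 1.2,
                  2e-5, -1.5e-5, 1), 3, 3, byrow = TRUE)
    tf <- matrix_transform(H)
    fx <- make_synthetic_slice(allen, sp, cells_per_region,
                               true_transform = tf, seed = seed + i,
                               dir = tempfile("sim"), name = id)
    file.copy(fx$paths$tiff, file.path(dir, "images", paste0(id, ".tif")),
              overwrite = TRUE)
    file.copy(fx$paths$points_csv,
              file.path(dir, "roi_coordinates", paste0(id, ".csv")),
              overwrite = TRUE)
    file.copy(fx$paths$landmarks_csv,
              file.path(dir, "landmarks", paste0(id, ".csv")),
              overwrite = TRUE)
    truth[[id]] <- fx
    slices[[i]] <- list(id = id, position_mm = positions[i],
                        dv_tilt_deg = 0, ml_tilt_deg = 0)
  }
  cfg <- list(
    plane = "coronal", pixel_size_um = 0.5, atlas_voxel_um = 10,
    canvas = as.integer(canvas_shape(allen, "coronal")),
    transform_family = "projective", strict_landmarks = TRUE,
    variant = "allen",
    bregma_voxel = as.integer(allen$bregma_voxel),
    atlases = list(
      allen = list(annotation = "atlas/allen_annotation.npy",
                   tree = "atlas/allen_tree.csv"),
      chon = list(annotation = "atlas/chon_annotation.npy",
                  tree = "atlas/chon_tree.csv")),
    slices = slices)
  cfg_path <- file.path(dir, "project.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(config = cfg_path, truth = truth))
}
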