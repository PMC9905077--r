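# End-to-end orchestration: phantom -> staining -> electrode -> projection
# -> MAR -> normalization -> frame -> morphometry -> trauma, with all
# outputs, a manifest and a log written to a run directory.

#' Build a run configuration
#'
#' All knobs of [run_end_to_end()] in one serializable list. Every source of
#' randomness derives from the single `seed`.
#'
#' @param phantom Named list of [phantom_spec()] arguments.
#' @param stain_time_h Submersion time for the rendered grey volume.
#' @param electrode `NULL` (no insertion) or a list with `depth_deg`,
#'   optional `lesions` (list of [lesion()] argument lists) and
#'   `radius_um`.
#' @param acquisition List: `n_angles`, `noise_sd`, `slices` (number of
#'   central slices simulated through the projector).
#' @param mar List: `threshold` (1/mm), `reinsert_metal`.
#' @param normalize List: `lo_pct`, `hi_pct`, `target_a`, `target_b`.
#' @param analysis List: `downsample_factor`, `thickness_step`,
#'   `hist_bin_mm`, `hist_start_mm`.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = list(grid_dim = c(128L, 128L, 128L),
                                      voxel_size_um = 84),
                       stain_time_h = 72,
                       electrode = list(depth_deg = 380,
                                        lesions = list(),
                                        radius_um = 220),
                       acquisition = list(n_angles = 180, noise_sd = 0.002,
                                          slices = 8),
                       mar = list(threshold = 1.0, reinsert_metal = TRUE),
                       normalize = list(lo_pct = 0.1, hi_pct = 99.9,
                                        target_a = 220, target_b = 60),
                       analysis = list(downsample_factor = 1L,
                                       thickness_step = 2L,
                                       hist_bin_mm = NULL,
                                       hist_start_mm = 0),
                       seed = 1L) {
  structure(list(phantom = phantom, stain_time_h = stain_time_h,
                 electrode = electrode, acquisition = acquisition,
                 mar = mar, normalize = normalize, analysis = analysis,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

log_line <- function(con, ...) {
  msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 paste0(...))
  writeLines(msg, con)
  invisible(msg)
}

#' Run the full analysis chain
#'
#' Generates the phantom, renders the stained grey volume, optionally
#' inserts the electrode with lesions, simulates projections over a central
#' slab of slices, applies metal artifact reduction, windows and normalizes
#' the grey volume to the reference materials, fits the cochlear frame,
#' writes the dimension report, the round-window-membrane thickness
#' histogram, and (when an electrode is present) the trauma report. All
#' outputs plus a manifest with the configuration hash land in `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the main in-memory results and
#'   `manifest`.
#' @export
run_end_to_end <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con), add = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stage <- "phantom"
  result <- list()
  tryCatch({
    log_line(con, "stage phantom: generating spec")
    ph_args <- config$phantom
    ph_args$seed <- config$seed
    spec <- do.call(phantom_spec, ph_args)
    pre <- generate_phantom(spec)
    result$pre <- pre
    save_stack(to_uint16(pre$grey), file.path(out_dir, "phantom_grey.tif"))
    save_label_stack(pre$labels, file.path(out_dir, "phantom_labels.tif"))
    write.csv(pre$truth, file.path(out_dir, "ground_truth.csv"),
              row.names = FALSE)

    stage <- "staining"
    log_line(con, "stage staining: t = ", config$stain_time_h, " h")
    stained <- simulate_staining(pre, config$stain_time_h)
    save_stack(to_uint16(stained), file.path(out_dir, "stained_grey.tif"))

    stage <- "electrode"
    post <- NULL
    if (!is.null(config$electrode)) {
      log_line(con, "stage electrode: depth ", config$electrode$depth_deg,
               " deg")
      les <- lapply(config$electrode$lesions, function(a) do.call(lesion, a))
      post <- insert_electrode(pre, config$electrode$depth_deg, les,
                               electrode_radius_um =
                                 config$electrode$radius_um %||% 220)
      result$post <- post
    }

    stage <- "projection"
    acq <- config$acquisition
    tomo_src <- if (is.null(post)) stained else post$grey
    nz <- dim(tomo_src$data)[3]
    zs <- seq(max(1, nz %/% 2 - acq$slices %/% 2), length.out = acq$slices)
    slab <- cect_volume(tomo_src$data[, , zs, drop = FALSE],
                        tomo_src$voxel_size_um, 32L)
    angles <- seq(0, 360 - 360 / acq$n_angles, by = 360 / acq$n_angles)
    log_line(con, "stage projection: ", acq$n_angles, " angles x ",
             length(zs), " slices")
    proj <- forward_project(slab, angles, noise_sd = acq$noise_sd,
                            seed = config$seed)
    stage <- "mar"
    log_line(con, "stage mar: threshold ", config$mar$threshold)
    marr <- reduce_metal_artifacts(proj, config$mar$threshold,
                                   config$mar$reinsert_metal %||% TRUE)
    result$mar <- marr
    metrics <- list(
      metal_voxels = sum(marr$metal_mask$mask),
      streak_before = if (any(marr$metal_mask$mask))
        streak_metric(marr$uncorrected, marr$metal_mask) else NA,
      streak_after = if (any(marr$metal_mask$mask))
        streak_metric(marr$volume, marr$metal_mask) else NA)
    log_line(con, "stage mar: streak ", format(metrics$streak_before),
             " -> ", format(metrics$streak_after))

    stage <- "normalize"
    nrm <- config$normalize
    refs <- reference_pair_from_labels(pre$labels, nrm$target_a,
                                       nrm$target_b)
    win <- window_to_8bit(stained, nrm$lo_pct, nrm$hi_pct)
    norm8 <- normalize_to_references(win, refs)
    ds <- downsample(norm8, config$analysis$downsample_factor %||% 1L)
    norm_out <- norm8
    norm_out$data <- pmin(pmax(round(norm_out$data), 0), 255)
    save_stack(norm_out, file.path(out_dir, "normalized_8bit.tif"))
    result$normalized <- ds

    stage <- "frame"
    log_line(con, "stage frame: fitting cochlear coordinate system")
    labs <- if (is.null(post)) pre$labels else post$labels
    frame <- fit_frame(labs)
    write_frame_json(frame, file.path(out_dir, "frame.json"))
    dims <- measure_cochlea_dimensions(labs, frame)
    dims$turns <- count_turns(labs, frame)
    dims$volume_mm3 <- sum(vapply(
      setdiff(anatomy_structures(pre$labels), character(0)),
      function(s) structure_volume(pre$labels, s), numeric(1)))
    write.csv(dims, file.path(out_dir, "dimensions.csv"),
              row.names = FALSE)
    result$dimensions <- dims

    stage <- "thickness"
    log_line(con, "stage thickness: round window membrane")
    tm <- local_thickness(structure_mask(pre$labels, "rwm"),
                          config$analysis$thickness_step %||% 2L,
                          pre$labels$voxel_size_um)
    th <- thickness_histogram(tm, config$analysis$hist_bin_mm,
                              config$analysis$hist_start_mm %||% 0)
    write.csv(th, file.path(out_dir, "rwm_thickness_histogram.csv"),
              row.names = FALSE)
    result$thickness <- th

    stage <- "trauma"
    if (!is.null(post)) {
      log_line(con, "stage trauma: building report")
      rep <- build_trauma_report(pre, post, frame = frame)
      out <- as.data.frame(rep[, setdiff(names(rep), "slice_fractions")])
      write.csv(out, file.path(out_dir, "trauma_report.csv"),
                row.names = FALSE)
      result$trauma <- rep
      trauma_note <- "completed"
    } else {
      log_line(con, "stage trauma: skipped (no electrode configured)")
      trauma_note <- "skipped (no electrode configured)"
    }

    manifest <- list(config_hash = cfg_hash, seed = config$seed,
                     stages = c("phantom", "staining", "electrode",
                                "projection", "mar", "normalize", "frame",
                                "thickness", "trauma"),
                     trauma = trauma_note, mar_metrics = metrics,
                     grid = spec$grid_dim, voxel_size_um = spec$voxel_size_um)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
    log_line(con, "run complete")
  }, error = function(e) {
    log_line(con, "ERROR in stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rescale an attenuation volume to 16-bit for storage
to_uint16 <- function(volume) {
  arr <- volume$data
  hi <- max(arr)
  if (hi <= 0) hi <- 1
  cect_volume(array(round(pmin(pmax(arr / hi, 0), 1) * 65535), dim(arr)),
              volume$voxel_size_um, 16L)
}

# labels stored as 8-bit TIFF plus the JSON label-name map
save_label_stack <- function(labels, path) {
  v <- cect_volume(labels$data, labels$voxel_size_um, 8L)
  save_stack(v, path)
  jsonlite::write_json(as.list(labels$label_map),
                       paste0(sub("\\.tiff?$", "", path), "_labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
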