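#' Run configuration: defaults, validation, JSON round-trip
#'
#' A run configuration collects the acquisition and analysis parameters
#' shared across the pipeline. `default_run_config()` returns the standard
#' protocol values: the planar acquisition time grid ([cect_time_grid()]),
#' the microCT pixel size (11.52 um), the clinical CT voxel grid
#' (0.32 x 0.32 x 0.625 mm), the planar ROI width (100 px), the circular
#' ROI radius (5 px), segmentation defaults and the washout sampling times
#' (0, 24, 48 h). `load_run_config()` reads a JSON file, rejects unknown
#' keys (naming the offender), fills unset keys with defaults and
#' validates; `save_run_config()` writes JSON that round-trips through
#' `load_run_config()`.
#'
#' @param path JSON file path.
#' @param config a run configuration list.
#' @return A validated named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    times_h = cect_time_grid(),
    microct_pixel_size_mm = 0.01152,
    ct_voxel_size_mm = c(0.32, 0.32, 0.625),
    roi_width_px = 100,
    roi_radius_px = 5,
    voi_radius_vox = 5,
    segmentation = list(threshold_hu = NULL, min_component_voxels = 27),
    intercept = "difference",
    washout_times_h = c(0, 24, 48)
  ), class = "run_config")
}

validate_run_config <- function(cfg) {
  check_scalar_pos(cfg$microct_pixel_size_mm, "microct_pixel_size_mm")
  if (length(cfg$ct_voxel_size_mm) != 3L || any(cfg$ct_voxel_size_mm <= 0))
    stopf("`ct_voxel_size_mm` must be 3 positive values")
  if (any(diff(cfg$times_h) <= 0) || any(cfg$times_h < 0))
    stopf("`times_h` must be nonnegative and strictly increasing")
  check_scalar_pos(cfg$roi_width_px, "roi_width_px")
  check_scalar_pos(cfg$roi_radius_px, "roi_radius_px")
  if (!cfg$intercept %in% c("difference", "absolute"))
    stopf("`intercept` must be \"difference\" or \"absolute\"")
  thr <- cfg$segmentation$threshold_hu
  if (!is.null(thr) && !is.na(thr)) check_scalar_pos(thr, "threshold_hu")
  check_scalar_pos(cfg$segmentation$min_component_voxels,
                   "min_component_voxels")
  cfg
}

#' @rdname default_run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defs <- unclass(default_run_config())
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown))
    stopf("unknown configuration key: %s", unknown[1])
  if (!is.null(raw$segmentation)) {
    bad <- setdiff(names(raw$segmentation), names(defs$segmentation))
    if (length(bad)) stopf("unknown configuration key: segmentation.%s", bad[1])
    raw$segmentation <- modifyList(defs$segmentation,
                                   as.list(raw$segmentation))
  }
  cfg <- modifyList(defs, as.list(raw))
  # JSON integers parse as integer; keep every numeric leaf double so a
  # save/load round-trip is identical to the in-memory configuration
  cfg <- rapply(cfg, function(x) if (is.integer(x)) as.double(x) else x,
                how = "replace")
  # JSON null comes back as NULL and modifyList drops it; restore slot
  if (is.null(cfg$segmentation$threshold_hu))
    cfg$segmentation["threshold_hu"] <- list(NULL)
  structure(validate_run_config(cfg), class = "run_config")
}

#' @rdname default_run_config
#' @export
save_run_config <- function(config, path) {
  cfg <- unclass(config)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
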