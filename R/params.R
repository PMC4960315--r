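#' Analysis parameters
#'
#' Bundles every numeric rule of the tracking and niche-interaction pipeline
#' into a single validated list. The defaults are the published analysis
#' settings: a 5-pixel median filter window, tracks kept only when longer
#' than 10 detected frames, contact within 5 um, proximal within 25 um,
#' 1 um hysteresis on zone boundaries, merging of transient interactions
#' shorter than 200 s, and a 60 min short/long duration split.
#'
#' @param pixel_size_um Physical pixel size in micrometres per pixel
#'   (isotropic). Default 1, i.e. positions are reported in pixel units
#'   unless the acquisition is calibrated.
#' @param frame_interval_s Time between consecutive frames in seconds.
#' @param median_window_px Odd window size of the pre-detection median
#'   filter, in pixels.
#' @param intensity_threshold Manual intensity cutoff applied to the
#'   median-filtered image. No default is shipped: the cutoff is
#'   data-dependent and must be supplied (see [otsu_threshold()] for a
#'   convenience initializer).
#' @param min_object_area_px Minimum connected-component area (pixels) for a
#'   detection.
#' @param max_link_displacement_px Maximum frame-to-frame displacement (in
#'   pixels) considered when linking detections into tracks.
#' @param gap_memory_frames Number of frames a track may go undetected before
#'   it is closed.
#' @param min_track_frames Validity bound on track length: only tracks with
#'   strictly more than this many detected frames are kept.
#' @param contact_cutoff_um Contact zone cutoff `d_c` (um, boundary included).
#' @param proximal_cutoff_um Proximal zone cutoff `d_p` (um, boundary
#'   included).
#' @param hysteresis_um Schmitt-trigger margin `epsilon` (um): a state is only
#'   left when the distance passes the nominal cutoff by more than this.
#' @param merge_window_s Transient-merging window `tau_m` (s): interaction
#'   periods shorter than this are merged into matching neighbours.
#' @param long_duration_min Short/long split for interaction durations, in
#'   minutes; events at least this long are classed "long".
#' @param centroid_weighting `"binary"` (unweighted centroid over component
#'   pixels, the default) or `"intensity"` (intensity-weighted).
#' @param drift_correction Logical; apply lateral drift correction before
#'   detection.
#' @param rng_seed Integer seed for any stochastic step.
#'
#' @return A validated list of class `"analysis_params"`.
#' @examples
#' p <- analysis_params(intensity_threshold = 300)
#' p$contact_cutoff_um
#' @export
analysis_params <- function(pixel_size_um = 1,
                            frame_interval_s = 10,
                            median_window_px = 5,
                            intensity_threshold = NA_real_,
                            min_object_area_px = 9,
                            max_link_displacement_px = 20,
                            gap_memory_frames = 1,
                            min_track_frames = 10,
                            contact_cutoff_um = 5,
                            proximal_cutoff_um = 25,
                            hysteresis_um = 1,
                            merge_window_s = 200,
                            long_duration_min = 60,
                            centroid_weighting = c("binary", "intensity"),
                            drift_correction = TRUE,
                            rng_seed = 1L) {
  centroid_weighting <- match.arg(centroid_weighting)
  p <- list(
    pixel_size_um = as.numeric(pixel_size_um),
    frame_interval_s = as.numeric(frame_interval_s),
    median_window_px = as.integer(median_window_px),
    intensity_threshold = as.numeric(intensity_threshold),
    min_object_area_px = as.integer(min_object_area_px),
    max_link_displacement_px = as.numeric(max_link_displacement_px),
    gap_memory_frames = as.integer(gap_memory_frames),
    min_track_frames = as.integer(min_track_frames),
    contact_cutoff_um = as.numeric(contact_cutoff_um),
    proximal_cutoff_um = as.numeric(proximal_cutoff_um),
    hysteresis_um = as.numeric(hysteresis_um),
    merge_window_s = as.numeric(merge_window_s),
    long_duration_min = as.numeric(long_duration_min),
    centroid_weighting = centroid_weighting,
    drift_correction = isTRUE(drift_correction),
    rng_seed = as.integer(rng_seed)
  )
  class(p) <- "analysis_params"
  validate_params(p)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "analysis_params"))
  if (!is.finite(p$pixel_size_um) || p$pixel_size_um <= 0)
    stop("pixel_size_um must be > 0", call. = FALSE)
  if (!is.finite(p$frame_interval_s) || p$frame_interval_s <= 0)
    stop("frame_interval_s must be > 0", call. = FALSE)
  if (is.na(p$median_window_px) || p$median_window_px < 1 ||
      p$median_window_px %% 2 == 0)
    stop("median_window_px must be odd and >= 1", call. = FALSE)
  if (!(p$contact_cutoff_um > 0))
    stop("contact_cutoff_um must be > 0", call. = FALSE)
  if (!(p$contact_cutoff_um < p$proximal_cutoff_um))
    stop("contact_cutoff_um must be smaller than proximal_cutoff_um",
         call. = FALSE)
  if (p$hysteresis_um < 0 || p$hysteresis_um >= p$contact_cutoff_um)
    stop("hysteresis_um must satisfy 0 <= hysteresis_um < contact_cutoff_um",
         call. = FALSE)
  if (p$merge_window_s <= 0) stop("merge_window_s must be > 0", call. = FALSE)
  if (p$long_duration_min <= 0)
    stop("long_duration_min must be > 0", call. = FALSE)
  if (p$max_link_displacement_px <= 0)
    stop("max_link_displacement_px must be > 0", call. = FALSE)
  if (p$gap_memory_frames < 0)
    stop("gap_memory_frames must be >= 0", call. = FALSE)
  p
}

#' Load analysis parameters from a YAML config file
#'
#' Reads a flat YAML key-value file; keys missing from the file fall back to
#' the defaults of [analysis_params()], unknown keys are rejected, and the
#' assembled parameter set is validated (for example `contact_cutoff_um`
#' must be smaller than `proximal_cutoff_um`).
#'
#' @param config_path Path to a YAML file. An empty file yields the defaults.
#' @return A validated `"analysis_params"` list.
#' @export
load_params <- function(config_path) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  known <- names(formals(analysis_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_params, cfg)
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("<analysis_params>\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
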