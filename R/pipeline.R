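#' Run the full tracking and niche-interaction pipeline
#'
#' Orchestrates one reproducible analysis run: input loading (or synthetic
#' simulation), lateral drift correction, per-frame cell detection, track
#' linking, short-track removal, gap interpolation, distance-field
#' classification with hysteresis, transient merging, duration classes,
#' and per-cell metrics. Every stage writes its CSV output under
#' `out_dir`, and a JSON run manifest records the resolved parameters,
#' input digests, per-stage counts and wall-clock times, so a re-run with
#' the same manifest reproduces identical outputs.
#'
#' @param config Either a path to a YAML config file or a list with
#'   elements:
#'   * `simulate`: arguments for [simulation_params()] (synthetic run), or
#'   * `inputs`: `movie`, `vascular_mask`, `endosteal_mask` file paths
#'     plus `pixel_size_um` and `frame_interval_s`;
#'   * `params`: overrides for [analysis_params()].
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the configured RNG seed if not `NULL`.
#' @param quiet Suppress per-stage log lines.
#' @return The run manifest (list), invisibly. Output files:
#'   `tracks.csv`, `zones.csv`, `events.csv`, `cell_metrics.csv`,
#'   `summary.csv`, `manifest.json` (plus simulation outputs for synthetic
#'   runs).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- proc.time()[["elapsed"]]
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # ---- pre-flight -----------------------------------------------------
  synthetic <- !is.null(config$simulate)
  if (!synthetic) {
    inp <- config$inputs
    if (is.null(inp))
      stop("config must contain either `simulate` or `inputs`",
           call. = FALSE)
    for (f in c("movie", "vascular_mask", "endosteal_mask"))
      if (is.null(inp[[f]]) || !file.exists(inp[[f]]))
        stop("pre-flight: input `", f, "` missing or not found",
             call. = FALSE)
    if (is.null(inp$pixel_size_um) || is.null(inp$frame_interval_s))
      stop("pre-flight: pixel_size_um and frame_interval_s are required",
           call. = FALSE)
  }
  par_over <- config$params %||% list()
  if (synthetic) {
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    if (!is.null(seed)) sim_args$rng_seed <- seed
    sim <- do.call(simulation_params, sim_args)
    par_over$pixel_size_um <- par_over$pixel_size_um %||% sim$pixel_size_um
    par_over$frame_interval_s <- par_over$frame_interval_s %||%
      sim$frame_interval_s
    par_over$intensity_threshold <- par_over$intensity_threshold %||%
      (sim$background_level + 0.25 * sim$spot_amplitude)
  } else {
    par_over$pixel_size_um <- par_over$pixel_size_um %||% inp$pixel_size_um
    par_over$frame_interval_s <- par_over$frame_interval_s %||%
      inp$frame_interval_s
  }
  if (!is.null(seed)) par_over$rng_seed <- seed
  params <- do.call(analysis_params, par_over)

  # ---- acquire inputs -------------------------------------------------
  input_digests <- list()
  if (synthetic) {
    simres <- clock("simulate", simulate_movie(sim, params = params))
    gt <- simres$ground_truth
    movie <- simres$movie
    rmap <- simres$region_map
    write_movie(movie, file.path(out_dir, "movie.tif"))
    write_region_maps(rmap, file.path(out_dir, "vascular_mask.tif"),
                      file.path(out_dir, "endosteal_mask.tif"))
    write_tracks(dplyr::mutate(
      gt$positions[, c("track_id", "frame", "x_px", "y_px")],
      interpolated = FALSE), file.path(out_dir, "truth_tracks.csv"))
    write_events(gt$events, file.path(out_dir, "truth_events.csv"))
    say("simulate: %d cells, %d frames, %d true events",
        sim$n_cells, sim$n_frames, nrow(gt$events))
  } else {
    movie <- clock("read", read_movie(inp$movie, inp$pixel_size_um,
                                      inp$frame_interval_s))
    rmap <- read_region_maps(inp$vascular_mask, inp$endosteal_mask,
                             inp$pixel_size_um,
                             expected_dim = frame_dim(movie))
    input_digests <- lapply(
      list(movie = inp$movie, vascular_mask = inp$vascular_mask,
           endosteal_mask = inp$endosteal_mask),
      function(p) unname(tools::md5sum(p)))
    gt <- NULL
  }
  if (rmap$vascular_empty || rmap$endosteal_empty)
    stop("pre-flight: classify stage needs nonempty vascular and ",
         "endosteal masks", call. = FALSE)

  # ---- preprocess + track --------------------------------------------
  drift <- clock("drift", {
    if (params$drift_correction) estimate_drift(movie)
    else tibble::tibble(frame = seq_len(n_frames(movie)) - 1L,
                        dx_px = 0, dy_px = 0)
  })
  corrected <- correct_drift(movie, drift)
  say("drift: max |offset| %.0f px", max(abs(c(drift$dx_px, drift$dy_px))))
  detections <- clock("detect", detect_movie(corrected, params))
  say("detect: %d detections in %d frames", nrow(detections),
      n_frames(movie))
  linked <- clock("link", link_detections(detections, params))
  kept <- filter_short_tracks(linked, params)
  tracks <- fill_gaps(kept)
  say("track: %d tracks linked, %d kept (> %d frames), %d samples after gap fill",
      dplyr::n_distinct(linked$track_id), dplyr::n_distinct(kept$track_id),
      params$min_track_frames, nrow(tracks))
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))

  # ---- classify -------------------------------------------------------
  fields <- region_distance_fields(rmap)
  cls <- clock("classify", classify_interactions(tracks, fields, params))
  pre_merge <- segment_events(cls$series, params$frame_interval_s)
  say("classify: %d events before merge, %d after", nrow(pre_merge),
      nrow(cls$events))
  readr::write_csv(cls$series, file.path(out_dir, "zones.csv"))
  write_events(cls$events, file.path(out_dir, "events.csv"))

  # ---- metrics --------------------------------------------------------
  metrics <- clock("metrics", {
    tf <- time_fractions(cls$series, cls$events, params)
    nd <- normalized_displacement(tracks, params)
    mv <- velocity_series(tracks, params) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(mean_velocity_um_min = mean(.data$v_um_min),
                       .groups = "drop")
    Reduce(function(a, b) dplyr::left_join(a, b, by = "track_id"),
           list(mv, nd, tf))
  })
  readr::write_csv(metrics, file.path(out_dir, "cell_metrics.csv"))
  summary_tab <- dplyr::bind_cols(
    count_periods(cls$events),
    tibble::tibble(
      n_cells = dplyr::n_distinct(tracks$track_id),
      relative_contact_frequency =
        suppressWarnings(relative_frequency(cls$events, "contact")),
      relative_proximal_frequency =
        suppressWarnings(relative_frequency(cls$events, "proximal"))))
  readr::write_csv(summary_tab, file.path(out_dir, "summary.csv"))
  say("metrics: %d interaction / %d no-interaction periods across %d cells",
      summary_tab$n_interaction, summary_tab$n_no_interaction,
      summary_tab$n_cells)

  # ---- manifest -------------------------------------------------------
  manifest <- list(
    tool = paste0("nichetrackr ",
                  as.character(utils::packageVersion("nichetrackr"))),
    seed = params$rng_seed,
    synthetic = synthetic,
    params = unclass(params),
    input_digests = input_digests,
    outputs = list(tracks = "tracks.csv", zones = "zones.csv",
                   events = "events.csv", cell_metrics = "cell_metrics.csv",
                   summary = "summary.csv"),
    counts = list(
      frames = n_frames(movie),
      detections = nrow(detections),
      tracks_linked = dplyr::n_distinct(linked$track_id),
      tracks_kept = dplyr::n_distinct(kept$track_id),
      events_before_merge = nrow(pre_merge),
      events_after_merge = nrow(cls$events)),
    timings_s = timings,
    total_s = round(proc.time()[["elapsed"]] - t_start, 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the tracking stage on a movie in memory
#'
#' Drift correction, per-frame detection, linking, short-track removal and
#' gap interpolation in one call — the "track" stage of [run_pipeline()]
#' for interactive use.
#'
#' @param movie A [movie_stack()].
#' @param params [analysis_params()] with `intensity_threshold` set.
#' @return A list with `drift` (tibble), `detections` (tibble) and
#'   `tracks` (gap-filled track tibble).
#' @export
track_movie <- function(movie, params) {
  drift <- if (params$drift_correction) estimate_drift(movie)
           else tibble::tibble(frame = seq_len(n_frames(movie)) - 1L,
                               dx_px = 0, dy_px = 0)
  corrected <- correct_drift(movie, drift)
  detections <- detect_movie(corrected, params)
  tracks <- fill_gaps(filter_short_tracks(
    link_detections(detections, params), params))
  list(drift = drift, detections = detections, tracks = tracks)
}
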