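sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Instantaneous cell velocity series
#'
#' `v(t) = |p(t) - p(t-1)| * pixel_size_um / frame_interval_s * 60`,
#' in um/min, defined from the second sample on. Raw consecutive
#' displacements are used (no smoothing) and interpolated samples are
#' included.
#'
#' @param tracks Track tibble (one or many tracks).
#' @param params [analysis_params()].
#' @return Tibble (`track_id`, `frame`, `v_um_min`).
#' @export
velocity_series <- function(tracks, params) {
  stopifnot(inherits(params, "analysis_params"))
  per_track_sizes <- table(tracks$track_id)
  if (any(per_track_sizes < 2L))
    stop("velocity undefined for single-sample track(s): ",
         paste(names(per_track_sizes)[per_track_sizes < 2L], collapse = ", "),
         call. = FALSE)
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(v_um_min =
      sqrt((.data$x_px - dplyr::lag(.data$x_px))^2 +
           (.data$y_px - dplyr::lag(.data$y_px))^2) *
      params$pixel_size_um /
      ((.data$frame - dplyr::lag(.data$frame)) * params$frame_interval_s) *
      60) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$v_um_min)) |>
    dplyr::select("track_id", "frame", "v_um_min")
}

#' Mean velocity by caller-supplied group
#'
#' Per-track mean velocities are averaged within groups (for example
#' "marrow" vs "in a blood vessel"); groups are kept independent, never
#' pooled. The grouping criterion is supplied by the caller.
#'
#' @param tracks Track tibble.
#' @param groups Tibble (`track_id`, `group`) assigning each track a label.
#' @param params [analysis_params()].
#' @return Tibble (`group`, `n_cells`, `mean_v_um_min`, `sem_v_um_min`).
#' @export
mean_velocity_by_group <- function(tracks, groups, params) {
  per_track <- velocity_series(tracks, params) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(mean_v = mean(.data$v_um_min), .groups = "drop")
  missing <- setdiff(groups$group, per_track |>
                       dplyr::inner_join(groups, by = "track_id") |>
                       dplyr::pull(.data$group))
  if (length(missing))
    warning("group(s) with no tracks omitted: ",
            paste(unique(missing), collapse = ", "))
  per_track |>
    dplyr::inner_join(groups, by = "track_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean_v_um_min = mean(.data$mean_v),
                     sem_v_um_min = sem(.data$mean_v),
                     .groups = "drop")
}

#' Normalized average displacement
#'
#' Displacement is the distance between a cell's current position and its
#' first recorded position; the average over all later timepoints is
#' normalized by the total time the cell was observed (in minutes), giving
#' um/min. The value is invariant under rigid rotations of the track.
#'
#' @param tracks Track tibble.
#' @param params [analysis_params()].
#' @return Tibble (`track_id`, `normalized_avg_displacement_um_min`).
#' @export
normalized_displacement <- function(tracks, params) {
  stopifnot(inherits(params, "analysis_params"))
  one <- function(tr) {
    if (nrow(tr) < 2L)
      stop("normalized displacement undefined for single-sample track ",
           tr$track_id[1], call. = FALSE)
    tr <- dplyr::arrange(tr, .data$frame)
    disp <- sqrt((tr$x_px - tr$x_px[1])^2 + (tr$y_px - tr$y_px[1])^2) *
      params$pixel_size_um
    span_min <- (tr$frame[nrow(tr)] - tr$frame[1]) *
      params$frame_interval_s / 60
    tibble::tibble(track_id = tr$track_id[1],
                   normalized_avg_displacement_um_min =
                     mean(disp[-1]) / span_min)
  }
  tracks |>
    dplyr::group_split(.data$track_id) |>
    purrr::map_dfr(one)
}

#' Per-cell time fractions near, in contact with and proximal to each niche
#'
#' "Time near" a region is defined directly from the per-frame distances
#' (fraction of frames with distance within the proximal cutoff), matching
#' the distance-based definition of the observation-time scatter plots.
#' Contact and proximal time fractions are computed from the merged
#' interaction events (fraction of the observed span covered by events of
#' that region and zone), since those are interactions. For each region,
#' contact + proximal + distal fractions sum to one, with the distal
#' fraction reported as the remainder of the observed span.
#'
#' @param series Labelled zone series ([label_timepoints()]).
#' @param events Merged, classified events for the same tracks.
#' @param params [analysis_params()].
#' @return Tibble with one row per track: near/contact/proximal/distal
#'   fractions per region.
#' @export
time_fractions <- function(series, events, params) {
  stopifnot(inherits(params, "analysis_params"))
  near <- series |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      fraction_time_near_vascular =
        mean(.data$d_v_um <= params$proximal_cutoff_um),
      fraction_time_near_endosteal =
        mean(.data$d_e_um <= params$proximal_cutoff_um),
      .groups = "drop")
  span <- events |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(span_s = sum(.data$duration_s), .groups = "drop")
  frac_of <- function(lab, zn, name) {
    events |>
      dplyr::filter(.data$label == lab,
                    !is.na(.data$zone), .data$zone == zn) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(t = sum(.data$duration_s), .groups = "drop") |>
      dplyr::right_join(span, by = "track_id") |>
      dplyr::transmute(.data$track_id,
                       !!name := dplyr::coalesce(.data$t, 0) / .data$span_s)
  }
  out <- near |>
    dplyr::left_join(frac_of("vascular", "contact",
                             "fraction_time_contact_vascular"),
                     by = "track_id") |>
    dplyr::left_join(frac_of("vascular", "proximal",
                             "fraction_time_proximal_vascular"),
                     by = "track_id") |>
    dplyr::left_join(frac_of("endosteal", "contact",
                             "fraction_time_contact_endosteal"),
                     by = "track_id") |>
    dplyr::left_join(frac_of("endosteal", "proximal",
                             "fraction_time_proximal_endosteal"),
                     by = "track_id")
  dplyr::mutate(out,
    fraction_time_distal_vascular =
      1 - .data$fraction_time_contact_vascular -
      .data$fraction_time_proximal_vascular,
    fraction_time_distal_endosteal =
      1 - .data$fraction_time_contact_endosteal -
      .data$fraction_time_proximal_endosteal)
}

#' Incidence of interactions per cell
#'
#' For each region and duration class, the mean (+/- s.e.m.) over cells of
#' the per-cell event count. Cells present in the event table but without
#' events of a given class count as zero.
#'
#' @param events Merged, classified event tibble. An optional `population`
#'   column stratifies the summary; otherwise a single population
#'   `"all"` is reported.
#' @return Tibble (`population`, `label`, `duration_class`, `n_cells`,
#'   `mean_incidence`, `sem_incidence`).
#' @export
incidence_per_cell <- function(events) {
  if (!"population" %in% names(events)) events$population <- "all"
  cells <- dplyr::distinct(events, .data$population, .data$track_id)
  grid <- tidyr::expand_grid(
    cells,
    label = c("vascular", "endosteal"),
    duration_class = c("short", "long"))
  counts <- events |>
    dplyr::filter(.data$label %in% c("vascular", "endosteal")) |>
    dplyr::count(.data$population, .data$track_id, .data$label,
                 .data$duration_class)
  grid |>
    dplyr::left_join(counts,
                     by = c("population", "track_id", "label",
                            "duration_class")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$population, .data$label, .data$duration_class) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean_incidence = mean(.data$n),
                     sem_incidence = sem(.data$n),
                     .groups = "drop")
}

#' Relative vascular/endosteal interaction frequency
#'
#' Ratio of total time spent in a given zone with the vascular region over
#' the same with the endosteal region (the default, time-weighted reading);
#' `mode = "count"` uses event counts instead. A zero denominator yields
#' `NA` with a warning, never an error.
#'
#' @param events Merged, classified event tibble.
#' @param zone `"contact"` or `"proximal"`.
#' @param mode `"time"` (default) or `"count"`.
#' @return A single numeric ratio (or `NA` if undefined).
#' @export
relative_frequency <- function(events, zone = c("contact", "proximal"),
                               mode = c("time", "count")) {
  zone <- match.arg(zone)
  mode <- match.arg(mode)
  zev <- dplyr::filter(events, !is.na(.data$zone), .data$zone == zone)
  agg <- function(lab) {
    sel <- dplyr::filter(zev, .data$label == lab)
    if (mode == "time") sum(sel$duration_s) else nrow(sel)
  }
  num <- agg("vascular"); den <- agg("endosteal")
  if (den == 0) {
    warning("no endosteal ", zone, " time: relative frequency undefined")
    return(NA_real_)
  }
  num / den
}

#' Distance histogram over all cell-frames
#'
#' Counts of per-frame distances to one region in right-open bins
#' `[k*w, (k+1)*w)` covering `[0, max distance]`; the counts sum to the
#' number of cell-frames.
#'
#' @param series Zone series with `d_v_um`/`d_e_um` columns.
#' @param region `"vascular"` or `"endosteal"`.
#' @param bin_width_um Bin width in micrometres, > 0.
#' @return Tibble (`bin_left_um`, `bin_right_um`, `count`).
#' @export
distance_histogram <- function(series, region = c("vascular", "endosteal"),
                               bin_width_um = 1) {
  region <- match.arg(region)
  if (bin_width_um <= 0) stop("bin_width_um must be > 0", call. = FALSE)
  d <- if (region == "vascular") series$d_v_um else series$d_e_um
  k <- floor(d / bin_width_um)
  kmax <- max(k, 0)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  tibble::tibble(
    bin_left_um = (seq_len(kmax + 1L) - 1L) * bin_width_um,
    bin_right_um = seq_len(kmax + 1L) * bin_width_um,
    count = counts)
}

#' Zone incidence and mean distance per zone
#'
#' For a set of cell observations (one row per cell for static snapshots,
#' or per cell-frame), reports the number of observations per zone and the
#' mean +/- s.e.m. distance within each zone. Empty zones report count 0
#' and an undefined (`NA`) mean.
#'
#' @param distances Tibble with a `d_um` column (and any id columns).
#' @param params [analysis_params()].
#' @return Tibble (`zone`, `count`, `mean_d_um`, `sem_d_um`) with zones in
#'   contact/proximal/distal order.
#' @export
zone_incidence_and_mean_distance <- function(distances, params) {
  stopifnot(inherits(params, "analysis_params"))
  zones <- c("contact", "proximal", "distal")
  z <- classify_zone(distances$d_um, params)
  purrr::map_dfr(zones, function(zn) {
    d <- distances$d_um[z == zn]
    tibble::tibble(zone = zn, count = length(d),
                   mean_d_um = if (length(d)) mean(d) else NA_real_,
                   sem_d_um = if (length(d) > 1) sem(d) else NA_real_)
  })
}

#' Spatial occupancy map
#'
#' 2D histogram of all cell positions over all frames on the movie grid,
#' optionally Gaussian-smoothed, normalized to sum to one — the probability
#' map of where associations occur.
#'
#' @param tracks Track tibble on the movie grid.
#' @param dim Grid dimensions `c(H, W)` in pixels.
#' @param smoothing_sigma_px Gaussian smoothing bandwidth in pixels
#'   (0 = none).
#' @return An `H x W` matrix summing to 1.
#' @export
occupancy_map <- function(tracks, dim, smoothing_sigma_px = 0) {
  H <- dim[1]; W <- dim[2]
  counts <- matrix(0, H, W)
  r <- pmin(pmax(round(tracks$y_px) + 1, 1), H)
  c <- pmin(pmax(round(tracks$x_px) + 1, 1), W)
  for (i in seq_along(r)) counts[r[i], c[i]] <- counts[r[i], c[i]] + 1
  if (smoothing_sigma_px > 0) {
    counts <- gaussian_blur(counts, smoothing_sigma_px)
  }
  counts / sum(counts)
}

# separable Gaussian convolution with zero boundary (mass renormalized by
# the caller)
gaussian_blur <- function(m, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  offs <- -half:half
  k <- exp(-offs^2 / (2 * sigma^2))
  k <- k / sum(k)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (j in seq_along(offs)) {
      i <- seq_len(n)
      tgt <- i + offs[j]
      ok <- tgt >= 1 & tgt <= n
      B[cbind(tgt[ok], i[ok])] <- B[cbind(tgt[ok], i[ok])] + k[j]
    }
    B
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}
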