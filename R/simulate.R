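#' Simulation parameters for synthetic intravital movies
#'
#' Defines a synthetic imaging experiment: Gaussian-spot cells on a noisy
#' background, a vascular ribbon and an endosteal border band, biased
#' random-walk motion with dwell states near the niche regions, optional
#' global lateral drift, and intermittent single-frame disappearance
#' (z-excursions). The defaults describe the package's standard validation
#' scenario: a 256 x 256 px field at 1 um/px, 10 s frame interval,
#' 200 frames, 10 cells, bright spots (amplitude 1000, sigma 3 px) on a
#' background of 100 counts with 1% Gaussian noise, and a stabilized
#' (zero-drift) field; a drifting variant is available via
#' `drift_per_frame`.
#'
#' Cell motion is an anchored walk: each cell owns one anchor per
#' behavioural state (`dwell_vascular` inside the vessel, `dwell_endosteal`
#' on the cavity-facing edge of the endosteal band, `free` in the distal
#' marrow space), placed on per-cell horizontal lanes so that trajectories
#' of different cells never approach each other. While anchored, the cell
#' wobbles around the anchor (Gaussian jitter `step_sd_dwell_px` /
#' `step_sd_free_px`) and may switch state according to
#' `transition_matrix`; switching re-targets the anchor and the cell
#' relocates in a persistent, directed transit at `max_step_px` per frame
#' with small lateral noise (`step_sd_transit_px`). State decisions and
#' z-excursions are made only while anchored, so transits are straight,
#' few-frame dashes between niches: niche exchanges are near-instantaneous
#' on the frame-interval scale and the true distance series crosses each
#' classification boundary within a single frame step, which keeps the
#' ground-truth event segmentation unambiguous. (Real cells migrate more
#' slowly and less straight; the methods vignette discusses what this
#' idealization does and does not validate.)
#'
#' @param dim Grid `c(H, W)` in pixels.
#' @param pixel_size_um,frame_interval_s Physical calibration.
#' @param n_frames,n_cells Movie length and cell count (`n_cells >= 0`).
#' @param spot_sigma_px,spot_amplitude Gaussian spot shape (sigma > 0).
#' @param background_level,noise_sd Additive background and Gaussian noise
#'   (counts).
#' @param texture_sd Standard deviation (counts) of the static tissue
#'   texture, a fixed speckle field that drifts with the field of view.
#'   Real marrow movies carry stationary autofluorescent structure; it is
#'   what makes drift registration identifiable, and the median filter
#'   suppresses it before detection.
#' @param drift_per_frame Global drift `c(dx, dy)` px/frame, may be
#'   fractional.
#' @param transition_matrix Row-stochastic 3x3 matrix over states
#'   (`dwell_vascular`, `dwell_endosteal`, `free`), rows = from.
#' @param init_probs Initial state probabilities; `NULL` uses the chain's
#'   stationary distribution.
#' @param step_sd_dwell_px,step_sd_free_px Positional wobble (px) around
#'   the anchor while in a dwell or free state.
#' @param step_sd_transit_px Lateral noise (px/frame) during directed
#'   transits (persistent migration is nearly straight).
#' @param attract_kappa Fraction of the anchor offset travelled per frame
#'   while uncapped (1 = relocate fully, then wobble).
#' @param max_step_px Cap on the deterministic step length (px/frame),
#'   i.e. the transit speed.
#' @param disappearance_prob Per-frame probability of a single-frame
#'   z-excursion (never two in a row, never at the track ends).
#' @param rng_seed Integer seed; identical seeds give bit-identical movies
#'   and ground truth.
#' @return A validated list of class `"simulation_params"`.
#' @export
simulation_params <- function(dim = c(256L, 256L),
                              pixel_size_um = 1,
                              frame_interval_s = 10,
                              n_frames = 200L,
                              n_cells = 10L,
                              spot_sigma_px = 3,
                              spot_amplitude = 1000,
                              background_level = 100,
                              noise_sd = 10,
                              texture_sd = 60,
                              drift_per_frame = c(0, 0),
                              transition_matrix = default_transition_matrix(),
                              init_probs = NULL,
                              step_sd_dwell_px = 0.4,
                              step_sd_free_px = 0.4,
                              step_sd_transit_px = 0.15,
                              attract_kappa = 1,
                              max_step_px = 16,
                              disappearance_prob = 0.01,
                              rng_seed = 1L) {
  states <- c("dwell_vascular", "dwell_endosteal", "free")
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(3L, 3L)))
    stop("transition_matrix must be 3x3", call. = FALSE)
  if (any(tm < 0) || any(tm > 1) || any(abs(rowSums(tm) - 1) > 1e-9))
    stop("transition_matrix rows must be probabilities summing to 1",
         call. = FALSE)
  dimnames(tm) <- list(states, states)
  if (is.null(init_probs)) init_probs <- stationary_probs(tm)
  if (length(init_probs) != 3L || any(init_probs < 0) ||
      abs(sum(init_probs) - 1) > 1e-9)
    stop("init_probs must be 3 probabilities summing to 1", call. = FALSE)
  if (spot_sigma_px <= 0) stop("spot_sigma_px must be > 0", call. = FALSE)
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  if (disappearance_prob < 0 || disappearance_prob >= 1)
    stop("disappearance_prob must be in [0, 1)", call. = FALSE)
  structure(list(
    dim = as.integer(dim), pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames), n_cells = as.integer(n_cells),
    spot_sigma_px = spot_sigma_px, spot_amplitude = spot_amplitude,
    background_level = background_level, noise_sd = noise_sd,
    texture_sd = texture_sd,
    drift_per_frame = as.numeric(drift_per_frame),
    transition_matrix = tm,
    init_probs = setNames(as.numeric(init_probs), states),
    step_sd_dwell_px = step_sd_dwell_px, step_sd_free_px = step_sd_free_px,
    step_sd_transit_px = step_sd_transit_px,
    attract_kappa = attract_kappa, max_step_px = max_step_px,
    disappearance_prob = disappearance_prob,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_params")
}

#' @rdname simulation_params
#' @export
default_transition_matrix <- function() {
  matrix(c(0.995, 0,     0.005,
           0,     0.995, 0.005,
           0.005, 0.005, 0.990),
         nrow = 3, byrow = TRUE)
}

stationary_probs <- function(tm) {
  p <- rep(1 / 3, 3)
  for (i in seq_len(2000)) p <- as.vector(p %*% tm)
  p / sum(p)
}

#' Default synthetic niche geometry
#'
#' A vertical vascular ribbon of fixed width and an endosteal band along
#' the left image border, non-overlapping — a minimal abstraction of a
#' sinusoidal vessel running through the marrow cavity with bone at the
#' field edge.
#'
#' @param dim Grid `c(H, W)` in pixels; at least 32 x 32.
#' @param pixel_size_um Micrometres per pixel.
#' @param vessel_halfwidth_px Ribbon half-width in pixels.
#' @param vessel_center_frac Horizontal position of the ribbon centreline
#'   as a fraction of the width.
#' @param endosteal_band_px Width of the border band in pixels.
#' @return A [region_map()].
#' @export
make_default_region_map <- function(dim, pixel_size_um = 1,
                                    vessel_halfwidth_px = 8L,
                                    vessel_center_frac = 0.5625,
                                    endosteal_band_px = 6L) {
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  cx <- as.integer(round(vessel_center_frac * W))   # 1-based centre column
  v_lo <- cx - as.integer(vessel_halfwidth_px)
  v_hi <- cx + as.integer(vessel_halfwidth_px)
  if (H < 32L || W < 32L || v_lo <= endosteal_band_px + 2L || v_hi >= W)
    stop("grid too small for both niche structures (need >= 32x32 px and ",
         "disjoint vessel/endosteum)", call. = FALSE)
  v <- matrix(FALSE, H, W); v[, v_lo:v_hi] <- TRUE
  e <- matrix(FALSE, H, W); e[, seq_len(as.integer(endosteal_band_px))] <- TRUE
  region_map(v, e, pixel_size_um)
}

step_is_capped <- function(x, y, tx, ty, sim) {
  sim$attract_kappa * sqrt((tx - x)^2 + (ty - y)^2) > sim$max_step_px
}

# anchor x positions (0-based) per state for the default geometry
anchor_positions <- function(sim, region_map) {
  W <- sim$dim[2]; H <- sim$dim[1]
  v_cols <- which(apply(region_map$vascular_mask, 2, any))
  e_cols <- which(apply(region_map$endosteal_mask, 2, any))
  # endosteal dwellers sit on the inner (cavity-facing) edge of the band so
  # their spots are not clipped by the image border
  ax <- c(dwell_vascular = mean(v_cols) - 1,
          dwell_endosteal = max(e_cols) - 1,
          free = round(0.28 * W))
  lanes <- (seq_len(max(sim$n_cells, 1L)) * H) / (sim$n_cells + 1L)
  list(x = ax, lanes = lanes)
}

#' Simulate ground truth for a synthetic movie
#'
#' Generates the complete ground truth of a synthetic experiment: true
#' per-cell positions per frame (pre-drift), behavioural states, per-frame
#' visibility flags (single-frame z-excursions), the global drift table,
#' and the true interaction events. The true `(label, zone)` series and
#' event list are computed from the true positions with the package's own
#' classifier ([classify_interactions()]), so they are exactly the
#' segmentation the pipeline should reproduce.
#'
#' @param sim A [simulation_params()].
#' @param region_map A [region_map()] on the simulation grid; `NULL` uses
#'   [make_default_region_map()].
#' @param params [analysis_params()] used for the true classification;
#'   `NULL` uses defaults with the simulation's calibration.
#' @return An object of class `"ground_truth"`: a list with `positions`
#'   (tibble `track_id, frame, x_px, y_px, state, visible`), `drift`,
#'   `series`, `events`, `region_map`, `sim` and `params`.
#' @export
simulate_ground_truth <- function(sim, region_map = NULL, params = NULL) {
  stopifnot(inherits(sim, "simulation_params"))
  if (is.null(region_map))
    region_map <- make_default_region_map(sim$dim, sim$pixel_size_um)
  if (is.null(params))
    params <- analysis_params(pixel_size_um = sim$pixel_size_um,
                              frame_interval_s = sim$frame_interval_s,
                              intensity_threshold = sim$background_level +
                                0.25 * sim$spot_amplitude)
  set.seed(sim$rng_seed)
  H <- sim$dim[1]; W <- sim$dim[2]
  states <- colnames(sim$transition_matrix)
  anch <- anchor_positions(sim, region_map)
  n <- sim$n_cells; Tn <- sim$n_frames
  # jitter the lanes: cells do not lodge on a regular lattice, and exact
  # periodicity would put a spurious sidelobe in the registration
  # cross-correlation
  if (n > 0) anch$lanes <- anch$lanes + runif(n, -3, 3)
  pos_list <- vector("list", max(n, 0L))
  for (i in seq_len(n)) {
    st <- character(Tn)
    x <- numeric(Tn); y <- numeric(Tn)
    in_transit <- logical(Tn)
    st[1] <- sample(states, 1, prob = sim$init_probs)
    x[1] <- anch$x[[st[1]]] + rnorm(1, 0, 1)
    y[1] <- anch$lanes[i] + rnorm(1, 0, 1)
    wobble_sd <- function(s)
      if (s == "free") sim$step_sd_free_px else sim$step_sd_dwell_px
    for (t in seq_len(Tn)[-1]) {
      # state decisions are made while anchored; mid-transit the cell keeps
      # migrating towards its committed anchor
      tx <- anch$x[[st[t - 1]]]; ty <- anch$lanes[i]
      if (step_is_capped(x[t - 1], y[t - 1], tx, ty, sim)) {
        st[t] <- st[t - 1]
      } else {
        st[t] <- sample(states, 1,
                        prob = sim$transition_matrix[st[t - 1], ])
        tx <- anch$x[[st[t]]]
      }
      dx <- sim$attract_kappa * (tx - x[t - 1])
      dy <- sim$attract_kappa * (ty - y[t - 1])
      sl <- sqrt(dx^2 + dy^2)
      if (sl > sim$max_step_px) {
        dx <- dx * sim$max_step_px / sl
        dy <- dy * sim$max_step_px / sl
        in_transit[t] <- TRUE
        sdv <- sim$step_sd_transit_px
      } else {
        sdv <- wobble_sd(st[t])
      }
      x[t] <- x[t - 1] + dx + rnorm(1, 0, sdv)
      y[t] <- y[t - 1] + dy + rnorm(1, 0, sdv)
    }
    x <- pmin(pmax(x, 0), W - 1)
    y <- pmin(pmax(y, 0), H - 1)
    # single-frame z-excursions, drawn only while the cell sits at its
    # anchor (probing the niche); never at the track ends, never in two
    # consecutive frames, and never adjacent to a transit step so that the
    # flanking true positions bracket the excursion linearly
    vis <- runif(Tn) >= sim$disappearance_prob
    vis[1] <- TRUE; vis[Tn] <- TRUE
    for (t in seq_len(Tn)[-1]) {
      if (in_transit[t] || (t < Tn && in_transit[t + 1])) vis[t] <- TRUE
      if (!vis[t - 1]) vis[t] <- TRUE  # single-frame gaps only
    }
    pos_list[[i]] <- tibble::tibble(
      track_id = i, frame = seq_len(Tn) - 1L, x_px = x, y_px = y,
      state = st, visible = vis)
  }
  positions <- if (n > 0) dplyr::bind_rows(pos_list) else
    tibble::tibble(track_id = integer(0), frame = integer(0),
                   x_px = double(0), y_px = double(0),
                   state = character(0), visible = logical(0))
  drift <- tibble::tibble(
    frame = seq_len(Tn) - 1L,
    dx_px = (seq_len(Tn) - 1L) * sim$drift_per_frame[1],
    dy_px = (seq_len(Tn) - 1L) * sim$drift_per_frame[2])
  if (n > 0) {
    tr <- dplyr::mutate(positions[, c("track_id", "frame", "x_px", "y_px")],
                        interpolated = FALSE)
    cls <- classify_interactions(tr, region_distance_fields(region_map),
                                 params)
    series <- cls$series
    events <- cls$events
  } else {
    series <- tibble::tibble(track_id = integer(0), frame = integer(0),
                             t_s = double(0), d_v_um = double(0),
                             d_e_um = double(0), label = character(0),
                             zone = character(0))
    events <- segment_events(series, sim$frame_interval_s)
  }
  structure(list(positions = positions, drift = drift, series = series,
                 events = events, region_map = region_map, sim = sim,
                 params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d cells x %d frames, %d true events (%d interaction)\n",
    x$sim$n_cells, x$sim$n_frames, nrow(x$events),
    sum(x$events$label != "none")))
  invisible(x)
}

#' Render a synthetic movie from ground truth
#'
#' Each visible cell is rendered as an isotropic Gaussian spot at its
#' drifted position (fractional drift shifts spot centres; frames are
#' never resampled, keeping the ground truth exact); the additive
#' background and Gaussian noise are applied and intensities quantized to
#' 16-bit counts as a camera would. Invisible frames omit the spot; spot
#' centres outside the grid are clipped, not an error.
#'
#' @param gt A [simulate_ground_truth()] result.
#' @param sim Simulation parameters (defaults to the ones in `gt`).
#' @return A [movie_stack()].
#' @export
render_movie <- function(gt, sim = gt$sim) {
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(sim$rng_seed + 104729L)  # independent stream for pixel noise
  H <- sim$dim[1]; W <- sim$dim[2]
  Tn <- sim$n_frames
  half <- ceiling(4 * sim$spot_sigma_px)
  texture <- if (sim$texture_sd > 0)
    matrix(rnorm(H * W, 0, sim$texture_sd), H, W) else matrix(0, H, W)
  grid_x <- rep(seq_len(W) - 1, each = H)
  grid_y <- rep(seq_len(H) - 1, times = W)
  by_frame <- split(gt$positions, gt$positions$frame)
  frames <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dx <- gt$drift$dx_px[t]; dy <- gt$drift$dy_px[t]
    tex_t <- if (dx == 0 && dy == 0) texture else
      matrix(bilinear_sample(texture, grid_x - dx, grid_y - dy), H, W)
    f <- sim$background_level + tex_t
    if (sim$noise_sd > 0)
      f <- f + matrix(rnorm(H * W, 0, sim$noise_sd), H, W)
    pts <- by_frame[[as.character(t - 1L)]]
    if (!is.null(pts)) {
      pts <- pts[pts$visible, , drop = FALSE]
      for (j in seq_len(nrow(pts))) {
        cx <- pts$x_px[j] + gt$drift$dx_px[t]
        cy <- pts$y_px[j] + gt$drift$dy_px[t]
        rr <- max(1L, floor(cy + 1 - half)):min(H, ceiling(cy + 1 + half))
        cc <- max(1L, floor(cx + 1 - half)):min(W, ceiling(cx + 1 + half))
        if (!length(rr) || !length(cc) || min(rr) > max(rr)) next
        gy <- exp(-((rr - 1) - cy)^2 / (2 * sim$spot_sigma_px^2))
        gx <- exp(-((cc - 1) - cx)^2 / (2 * sim$spot_sigma_px^2))
        f[rr, cc] <- f[rr, cc] + sim$spot_amplitude * outer(gy, gx)
      }
    }
    frames[[t]] <- pmin(pmax(round(f), 0), 65535)
  }
  movie_stack(frames, sim$pixel_size_um, sim$frame_interval_s,
              channel_name = "synthetic")
}

#' Simulate a complete synthetic experiment
#'
#' @inheritParams simulate_ground_truth
#' @return A list with `ground_truth`, `movie` and `region_map`.
#' @export
simulate_movie <- function(sim, region_map = NULL, params = NULL) {
  gt <- simulate_ground_truth(sim, region_map, params)
  list(ground_truth = gt, movie = render_movie(gt),
       region_map = gt$region_map)
}

#' Named simulation scenarios
#'
#' `scenario_default()` is the standard validation scenario (the
#' [simulation_params()] defaults). `scenario_contact_fraction()` tunes the
#' dwell/free switching probabilities of a two-state (vascular dwell vs
#' free) population so that the stationary occupancy of the vascular dwell
#' state — and hence the expected per-cell contact-time fraction — equals
#' `target_fraction`; it is the scenario used to check that the pipeline
#' recovers a known population contact-time fraction.
#'
#' @param rng_seed Integer seed.
#' @param ... Overrides passed on to [simulation_params()].
#' @param target_fraction Stationary probability of the vascular dwell
#'   state.
#' @param leave_prob Per-frame probability of leaving the vascular dwell
#'   state.
#' @return A [simulation_params()] object.
#' @export
scenario_default <- function(rng_seed = 1L, ...) {
  simulation_params(rng_seed = rng_seed, ...)
}

#' @rdname scenario_default
#' @export
scenario_contact_fraction <- function(rng_seed = 1L,
                                      target_fraction = 0.7,
                                      leave_prob = 0.01, ...) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  enter_prob <- leave_prob * target_fraction / (1 - target_fraction)
  tm <- matrix(c(1 - leave_prob, 0, leave_prob,
                 0,              0, 1,
                 enter_prob,     0, 1 - enter_prob),
               nrow = 3, byrow = TRUE)
  simulation_params(rng_seed = rng_seed, transition_matrix = tm,
                    init_probs = c(target_fraction, 0, 1 - target_fraction),
                    ...)
}

#' Match pipeline tracks to ground-truth cells and score recovery
#'
#' Each pipeline track is assigned to the ground-truth cell whose true
#' positions are closest on the frames the track covers. A ground-truth
#' (cell, frame) pair counts as recovered when the assigned track has a
#' sample at that frame within `tol_px` of the true position.
#'
#' @param gt A [simulate_ground_truth()] result.
#' @param tracks Pipeline track tibble (gap-filled, drift-corrected frame
#'   of reference).
#' @param tol_px Position tolerance in pixels.
#' @return A list: `frame_recovery` (fraction of ground-truth cell-frames
#'   recovered), `mapping` (tibble `track_id`, `true_id`), `n_tracks`,
#'   `max_err_px` (largest position error among matched frames).
#' @export
evaluate_tracking <- function(gt, tracks, tol_px = 1) {
  truth <- gt$positions
  if (nrow(tracks) == 0L)
    return(list(frame_recovery = 0, mapping = tibble::tibble(),
                n_tracks = 0L, max_err_px = Inf))
  joined <- dplyr::inner_join(
    tracks, truth, by = "frame", suffix = c("", "_true"),
    relationship = "many-to-many")
  joined$err <- sqrt((joined$x_px - joined$x_px_true)^2 +
                     (joined$y_px - joined$y_px_true)^2)
  mapping <- joined |>
    dplyr::group_by(.data$track_id, .data$track_id_true) |>
    dplyr::summarise(mean_err = mean(.data$err), .groups = "drop") |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_min(.data$mean_err, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(true_id = "track_id_true")
  matched <- joined |>
    dplyr::inner_join(mapping[, c("track_id", "true_id")],
                      by = "track_id") |>
    dplyr::filter(.data$track_id_true == .data$true_id)
  hit <- matched |>
    dplyr::filter(.data$err <= tol_px) |>
    dplyr::distinct(.data$true_id, .data$frame)
  list(frame_recovery = nrow(hit) / nrow(truth),
       mapping = mapping,
       n_tracks = dplyr::n_distinct(tracks$track_id),
       max_err_px = max(matched$err))
}

#' Compare pipeline events with ground-truth events
#'
#' Relabels pipeline events with the matched ground-truth cell ids (from
#' [evaluate_tracking()]) and compares the two event tables exactly on
#' `(track, label, zone, start_s, end_s, duration_class)`.
#'
#' @param gt A [simulate_ground_truth()] result.
#' @param events Pipeline event tibble.
#' @param mapping Track-to-truth mapping from [evaluate_tracking()].
#' @return A list: `identical` (logical), `n_matching` (events agreeing
#'   exactly), `n_true`, `n_pipeline`.
#' @export
compare_events <- function(gt, events, mapping) {
  canon <- function(ev) {
    ev |>
      dplyr::mutate(zone = dplyr::coalesce(.data$zone, ""),
                    duration_class = dplyr::coalesce(.data$duration_class,
                                                     "")) |>
      dplyr::select("track_id", "label", "zone", "start_s", "end_s",
                    "duration_class") |>
      dplyr::arrange(.data$track_id, .data$start_s)
  }
  pe <- events |>
    dplyr::inner_join(mapping[, c("track_id", "true_id")], by = "track_id") |>
    dplyr::mutate(track_id = .data$true_id) |>
    dplyr::select(-"true_id")
  a <- canon(gt$events); b <- canon(pe)
  key <- function(d) paste(d$track_id, d$label, d$zone, d$start_s, d$end_s,
                           d$duration_class)
  list(identical = identical(as.data.frame(a), as.data.frame(b)),
       n_matching = length(intersect(key(a), key(b))),
       n_true = nrow(a), n_pipeline = nrow(b))
}
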