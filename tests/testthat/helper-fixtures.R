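# Shared fixtures and independent oracles, built in code at test time.

# default parameter set with a detection threshold, for synthetic frames
test_params <- function(...) {
  analysis_params(intensity_threshold = 350, ...)
}

# small simulation used by unit tests (fast; full-size scenarios live in
# the acceptance suite)
small_sim <- function(seed, dim = c(128L, 128L), n_frames = 60L,
                      n_cells = 4L, ...) {
  simulation_params(dim = dim, n_frames = n_frames, n_cells = n_cells,
                    rng_seed = seed, ...)
}

# cyclically shift a matrix so content moves by (+dx, +dy) (x = column)
cyclic_shift <- function(m, dx, dy) {
  m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
    ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
}

# brute-force Euclidean distance to the nearest mask pixel, in um
bf_distance_field <- function(mask, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (c in seq_len(W))
    out[r, c] <- sqrt(min((r - idx[, 1])^2 + (c - idx[, 2])^2))
  out * pixel_size_um
}

# brute-force minimum distance from a real-valued point to any mask pixel
bf_point_distance <- function(mask, x, y, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  sqrt(min((idx[, 1] - 1 - y)^2 + (idx[, 2] - 1 - x)^2)) * pixel_size_um
}

# exhaustive-search optimum of the frame-pair correspondence problem:
# enumerate every injective partial matching between track heads A and
# detections B; cost = sum of squared displacements of matched pairs
# (only pairs within max_disp allowed) + max_disp^2 per unmatched object.
bf_match_cost <- function(A, B, max_disp) {
  nA <- nrow(A); nB <- nrow(B)
  P <- max_disp^2
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  best <- Inf
  recurse <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > nA) {
      total <- acc + (nB - sum(used)) * P
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1, used, acc + P)          # track i unmatched
    for (j in seq_len(nB)) {
      if (!used[j] && d2[i, j] <= P) {
        used[j] <- TRUE
        recurse(i + 1, used, acc + d2[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nB), 0)
  best
}

# cost actually incurred by the package solver on one frame pair
solver_match_cost <- function(A, B, max_disp) {
  m <- nichetrackr:::match_frame(A, B, max_disp)
  P <- max_disp^2
  cost <- 0
  matched_tracks <- stats::na.omit(m)
  for (j in seq_along(m)) {
    if (is.na(m[j])) cost <- cost + P
    else cost <- cost + sum((A[m[j], ] - B[j, ])^2)
  }
  cost + (nrow(A) - length(matched_tracks)) * P
}

# hand-built zone series for interaction tests
make_series <- function(d_v, d_e, frame_interval_s = 10, track_id = 1L) {
  tibble::tibble(track_id = track_id,
                 frame = seq_along(d_v) - 1L,
                 t_s = (seq_along(d_v) - 1L) * frame_interval_s,
                 d_v_um = d_v, d_e_um = d_e)
}

# hand-built event table that tiles a span
make_events <- function(track_id, labels, zones, durations,
                        frame_interval_s = 10) {
  end <- cumsum(durations)
  start <- end - durations
  tibble::tibble(track_id = track_id, label = labels, zone = zones,
                 start_s = start,
                 end_s = end - frame_interval_s,
                 duration_s = durations,
                 duration_class = NA_character_)
}
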