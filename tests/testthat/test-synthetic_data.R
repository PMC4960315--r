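test_that("identical seeds reproduce ground truth and movie bit-exactly", {
  sim <- small_sim(5)
  a <- simulate_ground_truth(sim)
  b <- simulate_ground_truth(sim)
  expect_identical(a$positions, b$positions)
  expect_identical(a$events, b$events)
  ma <- render_movie(a); mb <- render_movie(b)
  expect_identical(ma$frames, mb$frames)
  # a different seed gives different trajectories
  c <- simulate_ground_truth(small_sim(6))
  expect_false(identical(a$positions$x_px, c$positions$x_px))
})

test_that("zero cells yield an empty track set and no events", {
  gt <- simulate_ground_truth(small_sim(1, n_cells = 0L))
  expect_equal(nrow(gt$positions), 0)
  expect_equal(nrow(gt$events), 0)
  mv <- render_movie(gt)
  expect_equal(length(mv$frames), 60)
})

test_that("a cell locked in vascular dwell produces one full-span contact event", {
  lock <- diag(3)   # no transitions ever
  sim <- small_sim(2, n_cells = 1L, transition_matrix = lock,
                   init_probs = c(1, 0, 0), disappearance_prob = 0)
  gt <- simulate_ground_truth(sim)
  expect_true(all(gt$positions$state == "dwell_vascular"))
  expect_equal(nrow(gt$events), 1)
  expect_equal(gt$events$label, "vascular")
  expect_equal(gt$events$zone, "contact")
  expect_equal(gt$events$duration_s, 60 * 10)
  # and the ground-truth events equal a fresh application of the classifier
  redo <- classify_interactions(
    dplyr::mutate(gt$positions[, c("track_id", "frame", "x_px", "y_px")],
                  interpolated = FALSE),
    region_distance_fields(gt$region_map), gt$params)
  expect_identical(as.data.frame(gt$events), as.data.frame(redo$events))
})

test_that("rendering places Gaussian spots at drifted positions", {
  sim <- small_sim(3, n_cells = 1L, noise_sd = 0, background_level = 0,
                   texture_sd = 0, transition_matrix = diag(3),
                   init_probs = c(1, 0, 0), step_sd_dwell_px = 0,
                   disappearance_prob = 0)
  gt <- simulate_ground_truth(sim)
  mv <- render_movie(gt)
  p0 <- gt$positions[gt$positions$frame == 0, ]
  f0 <- mv$frames[[1]]
  peak <- which(f0 == max(f0), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak["col"] - 1), round(p0$x_px), tolerance = 1)
  expect_equal(unname(peak["row"] - 1), round(p0$y_px), tolerance = 1)
  expect_gt(max(f0), 0.85 * sim$spot_amplitude)  # peak ~ amplitude
  # unit x drift moves the spot one pixel per frame
  sim_d <- small_sim(3, n_cells = 1L, noise_sd = 0, background_level = 0,
                     texture_sd = 0, transition_matrix = diag(3),
                     init_probs = c(1, 0, 0), step_sd_dwell_px = 0,
                     disappearance_prob = 0, drift_per_frame = c(1, 0))
  gtd <- simulate_ground_truth(sim_d)
  mvd <- render_movie(gtd)
  for (t in c(5, 20)) {
    ft <- mvd$frames[[t + 1]]
    pk <- which(ft == max(ft), arr.ind = TRUE)[1, ]
    expect_equal(unname(pk["col"] - 1),
                 round(gtd$positions$x_px[t + 1] + t), tolerance = 1)
  }
})

test_that("detection on a zero-noise rendering recovers centroids to 0.5 px", {
  sim <- small_sim(4, noise_sd = 0, texture_sd = 0, disappearance_prob = 0)
  gt <- simulate_ground_truth(sim)
  mv <- render_movie(gt)
  det <- detect_movie(mv, gt$params)
  truth <- gt$positions
  j <- dplyr::inner_join(det, truth, by = "frame",
                         relationship = "many-to-many")
  j$err <- sqrt((j$x_px.x - j$x_px.y)^2 + (j$y_px.x - j$y_px.y)^2)
  nearest <- j |>
    dplyr::group_by(frame, track_id) |>
    dplyr::summarise(err = min(err), .groups = "drop")
  expect_equal(nrow(nearest), nrow(truth))
  expect_lt(max(nearest$err), 0.5)
})

test_that("default region map builds disjoint nonempty structures", {
  rm <- make_default_region_map(c(256L, 256L), 1)
  expect_gt(sum(rm$vascular_mask), 0)
  expect_gt(sum(rm$endosteal_mask), 0)
  expect_equal(sum(rm$vascular_mask & rm$endosteal_mask), 0)
  expect_error(make_default_region_map(c(4L, 4L), 1), "too small")
  # ribbon centreline to ribbon edge: half-width pixels, via brute force
  px <- 2
  rm2 <- make_default_region_map(c(64L, 64L), px, vessel_halfwidth_px = 8L)
  outside <- !rm2$vascular_mask
  v_cols <- range(which(apply(rm2$vascular_mask, 2, any)))
  centre_col <- mean(v_cols)
  bf <- bf_point_distance(outside, centre_col - 1, 32, px)
  expect_equal(bf, (8 + 1) * px)  # centreline to first outside pixel
})

test_that("ground-truth events equal the classifier applied to true distances", {
  # oracle closure on a scenario with z-excursions and transits
  sim <- small_sim(7)
  gt <- simulate_ground_truth(sim)
  fields <- region_distance_fields(gt$region_map)
  tr <- dplyr::mutate(gt$positions[, c("track_id", "frame", "x_px", "y_px")],
                      interpolated = FALSE)
  series <- label_timepoints(sample_distances(tr, fields, gt$params),
                             gt$params)
  events <- classify_durations(
    merge_transients(segment_events(series, sim$frame_interval_s),
                     gt$params), gt$params)
  expect_identical(as.data.frame(gt$events), as.data.frame(events))
  # visibility gaps are single-frame and interior
  vis <- gt$positions$visible
  gaps <- which(!vis)
  if (length(gaps)) {
    expect_false(any(diff(gaps) == 1 &
                       diff(gt$positions$track_id[gaps]) == 0))
  }
  expect_true(all(gt$positions$visible[gt$positions$frame == 0]))
})

test_that("simulation parameter validation rejects malformed inputs", {
  bad_tm <- matrix(c(0.5, 0.5, 0.5, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_error(simulation_params(transition_matrix = bad_tm), "summing to 1")
  expect_error(simulation_params(spot_sigma_px = 0), "spot_sigma_px")
  expect_error(simulation_params(n_cells = -1), "n_cells")
  expect_error(simulation_params(disappearance_prob = 1), "disappearance")
})
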