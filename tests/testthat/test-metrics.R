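mk_track <- function(id, x, y, frames = seq_along(x) - 1L) {
  tibble::tibble(track_id = id, frame = as.integer(frames),
                 x_px = x, y_px = y, interpolated = FALSE)
}

test_that("velocity series converts displacement to um/min", {
  p <- analysis_params(pixel_size_um = 1, frame_interval_s = 10)
  still <- mk_track(1L, rep(3, 5), rep(3, 5))
  expect_equal(velocity_series(still, p)$v_um_min, rep(0, 4))
  # 2 px/frame at 1 um/px and 10 s/frame -> 12 um/min
  moving <- mk_track(1L, seq(0, 18, by = 2), rep(0, 10))
  expect_equal(velocity_series(moving, p)$v_um_min, rep(12, 9))
  expect_error(velocity_series(mk_track(1L, 1, 1), p), "velocity undefined")
})

test_that("group velocities average per-track means with s.e.m.", {
  p <- analysis_params()
  # per-track mean velocities 6 and 12 um/min in one group
  tr <- dplyr::bind_rows(mk_track(1L, seq(0, 9), rep(0, 10)),
                         mk_track(2L, seq(0, 18, 2), rep(0, 10)))
  groups <- tibble::tibble(track_id = 1:2, group = "marrow")
  out <- mean_velocity_by_group(tr, groups, p)
  expect_equal(out$mean_v_um_min, 9)
  expect_equal(out$sem_v_um_min, 3)
  # groups stay independent
  groups2 <- tibble::tibble(track_id = 1:2, group = c("marrow", "vessel"))
  out2 <- mean_velocity_by_group(tr, groups2, p)
  expect_equal(sort(out2$mean_v_um_min), c(6, 12))
  groups3 <- tibble::tibble(track_id = c(1L, 2L, 99L),
                            group = c("marrow", "marrow", "vessel"))
  expect_warning(mean_velocity_by_group(tr, groups3, p), "no tracks")
})

test_that("normalized displacement matches hand arithmetic and rotation", {
  p <- analysis_params(pixel_size_um = 1, frame_interval_s = 10)
  still <- mk_track(1L, rep(1, 6), rep(2, 6))
  expect_equal(normalized_displacement(still, p)[[2]], 0)
  # straight motion 1 um/frame over 10 intervals: mean(1..10)/(100s/60)
  straight <- mk_track(1L, 0:10, rep(0, 11))
  expect_equal(normalized_displacement(straight, p)[[2]],
               5.5 / (100 / 60))
  th <- 0.7  # arbitrary rigid rotation preserves the value
  rot <- mk_track(1L, cos(th) * (0:10), sin(th) * (0:10))
  expect_equal(normalized_displacement(rot, p)[[2]], 5.5 / (100 / 60))
})

test_that("time fractions follow distances for 'near' and events for zones", {
  p <- analysis_params()
  s <- make_series(d_v = rep(2, 100), d_e = rep(50, 100))
  lab <- label_timepoints(s, p)
  ev <- classify_durations(merge_transients(
    segment_events(lab, 10), p), p)
  tf <- time_fractions(lab, ev, p)
  expect_equal(tf$fraction_time_near_vascular, 1)
  expect_equal(tf$fraction_time_near_endosteal, 0)
  expect_equal(tf$fraction_time_contact_vascular, 1)
  expect_equal(tf$fraction_time_distal_vascular, 0)
  # half the frames near the vasculature
  s2 <- make_series(d_v = c(rep(10, 50), rep(40, 50)), d_e = rep(80, 100))
  lab2 <- label_timepoints(s2, p)
  ev2 <- classify_durations(merge_transients(
    segment_events(lab2, 10), p), p)
  tf2 <- time_fractions(lab2, ev2, p)
  expect_equal(tf2$fraction_time_near_vascular, 0.5)
  # per-region fractions always close to one
  sums_v <- tf2$fraction_time_contact_vascular +
    tf2$fraction_time_proximal_vascular + tf2$fraction_time_distal_vascular
  expect_equal(sums_v, 1, tolerance = 1e-9)
})

test_that("incidence per cell averages counts with s.e.m., zeros included", {
  ev <- dplyr::bind_rows(
    make_events(1L, rep("vascular", 2), rep("contact", 2), c(300, 400)),
    make_events(2L, "vascular", "contact", 900))
  ev$duration_class <- "short"
  out <- incidence_per_cell(ev)
  vs <- out[out$label == "vascular" & out$duration_class == "short", ]
  expect_equal(vs$mean_incidence, 1.5)       # counts 2 and 1
  expect_equal(vs$sem_incidence, sd(c(2, 1)) / sqrt(2))
  es <- out[out$label == "endosteal" & out$duration_class == "short", ]
  expect_equal(es$mean_incidence, 0)
  # hand-rolled two-pass s.e.m. check on a random vector
  set.seed(61)
  x <- rnorm(17)
  mu <- sum(x) / length(x)
  two_pass <- sqrt(sum((x - mu)^2) / (length(x) - 1)) / sqrt(length(x))
  expect_equal(nichetrackr:::sem(x), two_pass)
})

test_that("relative frequency ratios time in zone, with undefined sentinel", {
  ev <- dplyr::bind_rows(
    make_events(1L, "vascular", "contact", 100),
    make_events(2L, "endosteal", "contact", 50))
  expect_equal(relative_frequency(ev, "contact"), 2)
  ev_eq <- dplyr::bind_rows(
    make_events(1L, "vascular", "proximal", 300),
    make_events(2L, "endosteal", "proximal", 300))
  expect_equal(relative_frequency(ev_eq, "proximal"), 1)
  ev_v <- make_events(1L, "vascular", "contact", 100)
  expect_warning(r <- relative_frequency(ev_v, "contact"), "undefined")
  expect_true(is.na(r))
  # count mode
  expect_equal(relative_frequency(ev, "contact", mode = "count"), 1)
})

test_that("distance histograms use right-open bins and conserve counts", {
  s <- make_series(d_v = rep(0, 25), d_e = rep(0, 25))
  h <- distance_histogram(s, "vascular", bin_width_um = 2)
  expect_equal(h$count[1], 25)
  expect_equal(sum(h$count), 25)
  s2 <- make_series(d_v = c(0, 1.99, 2, 3.5, 8), d_e = rep(0, 5))
  h2 <- distance_histogram(s2, "vascular", bin_width_um = 2)
  expect_equal(h2$count, c(2, 2, 0, 0, 1))   # 2 falls in [2, 4)
  expect_equal(sum(h2$count), 5)
  set.seed(62)
  s3 <- make_series(d_v = runif(2000, 0, 50), d_e = rep(0, 2000))
  h3 <- distance_histogram(s3, "vascular", bin_width_um = 5)
  expect_equal(sum(h3$count), 2000)
  # uniform distances: approximately flat (chi-square sanity check)
  chi <- sum((h3$count - 200)^2 / 200)
  expect_lt(chi, qchisq(0.999, df = 9))
})

test_that("zone incidence reports counts and ordered mean distances", {
  p <- analysis_params()
  d <- tibble::tibble(cell_id = 1:3, d_um = c(2, 10, 40))
  out <- zone_incidence_and_mean_distance(d, p)
  expect_equal(out$count, c(1, 1, 1))
  expect_equal(out$mean_d_um, c(2, 10, 40))
  allc <- tibble::tibble(cell_id = 1:4, d_um = c(0, 1, 2, 3))
  out2 <- zone_incidence_and_mean_distance(allc, p)
  expect_equal(out2$count, c(4, 0, 0))
  expect_true(is.na(out2$mean_d_um[2]))
  set.seed(63)
  mixed <- tibble::tibble(d_um = runif(200, 0, 60))
  out3 <- zone_incidence_and_mean_distance(mixed, p)
  ok <- !is.na(out3$mean_d_um)
  expect_true(all(diff(out3$mean_d_um[ok]) > 0))  # contact <= prox <= distal
})

test_that("occupancy maps are normalized and keep their maximum in place", {
  tr <- mk_track(1L, rep(10, 7), rep(20, 7))
  m <- occupancy_map(tr, dim = c(64, 64), smoothing_sigma_px = 0)
  expect_equal(sum(m), 1)
  expect_equal(m[21, 11], 1)   # row y+1, col x+1
  set.seed(64)
  cluster <- mk_track(1L, 30 + rnorm(300, 0, 1.5), 40 + rnorm(300, 0, 1.5))
  ms <- occupancy_map(cluster, dim = c(64, 64), smoothing_sigma_px = 2)
  expect_equal(sum(ms), 1, tolerance = 1e-12)
  peak <- which(ms == max(ms), arr.ind = TRUE)
  expect_lt(sqrt((peak[1] - 41)^2 + (peak[2] - 31)^2), 2.5)
})

test_that("metrics recomputed from the event CSV equal in-memory values", {
  p <- analysis_params()
  set.seed(65)
  d_v <- pmax(0, 12 + cumsum(rnorm(150, 0, 2)))
  s <- make_series(d_v = d_v, d_e = rep(70, 150))
  lab <- label_timepoints(s, p)
  ev <- classify_durations(merge_transients(segment_events(lab, 10), p), p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  ev2 <- read_events(path)
  expect_equal(suppressWarnings(relative_frequency(ev2, "contact")),
               suppressWarnings(relative_frequency(ev, "contact")))
  expect_equal(as.data.frame(time_fractions(lab, ev2, p)),
               as.data.frame(time_fractions(lab, ev, p)))
  expect_equal(as.data.frame(count_periods(ev2)),
               as.data.frame(count_periods(ev)))
})
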