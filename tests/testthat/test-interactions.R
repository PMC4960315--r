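test_that("timepoint labels follow the nearest region and its zone", {
  p <- analysis_params()
  s <- make_series(d_v = c(3, 3), d_e = c(40, 40))
  lab <- label_timepoints(s, p)
  expect_equal(lab$label, c("vascular", "vascular"))
  expect_equal(lab$zone, c("contact", "contact"))
  # exact tie at the first frame resolves to vascular
  s2 <- make_series(d_v = 10, d_e = 10)
  lab2 <- label_timepoints(s2, p)
  expect_equal(lab2$label, "vascular")
  expect_equal(lab2$zone, "proximal")
  expect_error(label_timepoints(make_series(c(1, NA), c(5, 5)), p),
               "missing distance")
})

test_that("hysteresis suppresses flicker around the contact boundary", {
  p <- analysis_params()   # d_c = 5, eps = 1
  osc <- rep(c(4.5, 5.5), 10)
  s <- make_series(d_v = osc, d_e = rep(60, 20))
  lab <- label_timepoints(s, p)
  expect_true(all(lab$zone == "contact"))   # leaving needs d > 6
  # crossing decisively past d_c + eps does leave contact
  s2 <- make_series(d_v = c(4, 6.5, 6.5), d_e = rep(60, 3))
  lab2 <- label_timepoints(s2, p)
  expect_equal(lab2$zone, c("contact", "proximal", "proximal"))
  # and the proximal->none exit needs d > d_p + eps
  s3 <- make_series(d_v = c(24, 25.5, 26.5), d_e = rep(60, 3))
  lab3 <- label_timepoints(s3, p)
  expect_equal(lab3$label, c("vascular", "vascular", "none"))
})

test_that("zero and unit hysteresis differ only within the margin", {
  set.seed(51)
  p1 <- analysis_params(hysteresis_um = 1)
  p0 <- analysis_params(hysteresis_um = 0)
  for (rep in 1:5) {
    d_v <- pmax(0, cumsum(rnorm(120, 0, 2)) + 10)
    s <- make_series(d_v = d_v, d_e = rep(80, 120))
    l1 <- label_timepoints(s, p1)
    l0 <- label_timepoints(s, p0)
    differ <- which(l1$zone != l0$zone | l1$label != l0$label)
    if (length(differ)) {
      near <- abs(d_v[differ] - 5) <= 1 | abs(d_v[differ] - 25) <= 1
      expect_true(all(near))
    }
  }
  expect_true(TRUE)  # at least assert the loop ran
})

test_that("segmentation produces maximal constant runs that tile the span", {
  p <- analysis_params()
  s <- make_series(d_v = rep(2, 100), d_e = rep(70, 100))
  ev <- segment_events(label_timepoints(s, p), 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 1000)
  expect_equal(ev$label, "vascular")
  # contact -> proximal -> endosteal proximal: exactly three periods
  s2 <- make_series(d_v = c(rep(2, 30), rep(10, 30), rep(40, 30)),
                    d_e = c(rep(70, 30), rep(70, 30), rep(12, 30)))
  ev2 <- segment_events(label_timepoints(s2, p), 10)
  expect_equal(ev2$label, c("vascular", "vascular", "endosteal"))
  expect_equal(ev2$zone, c("contact", "proximal", "proximal"))
  expect_equal(sum(ev2$duration_s), 900)
  expect_equal(nrow(segment_events(s2[0, ], 10)), 0)
})

test_that("transient merging follows the neighbour rules", {
  p <- analysis_params()  # merge window 200 s
  # sandwich: short 'none' between matching contacts fuses all three
  ev <- make_events(1L, c("vascular", "none", "vascular"),
                    c("contact", NA, "contact"), c(300, 100, 300))
  m <- merge_transients(ev, p)
  expect_equal(nrow(m), 1)
  expect_equal(m$label, "vascular")
  expect_equal(m$zone, "contact")
  expect_equal(m$duration_s, 700)
  # transient with two different flanks is kept
  ev2 <- make_events(1L, c("endosteal", "vascular", "none"),
                     c("proximal", "contact", NA), c(400, 150, 400))
  m2 <- merge_transients(ev2, p)
  expect_equal(nrow(m2), 3)
  expect_equal(m2$duration_s, c(400, 150, 400))
  # edge transient is absorbed into its only neighbour
  ev3 <- make_events(1L, c("none", "vascular"), c(NA, "contact"),
                     c(100, 800))
  m3 <- merge_transients(ev3, p)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$label, "vascular")
  expect_equal(m3$duration_s, 900)
  # nothing below the window: unchanged
  ev4 <- make_events(1L, c("vascular", "none"), c("contact", NA),
                     c(200, 250))
  expect_equal(as.data.frame(merge_transients(ev4, p)),
               as.data.frame(ev4))
})

test_that("merging is idempotent, conserves time, never adds events", {
  set.seed(52)
  p <- analysis_params()
  labels <- c("vascular", "endosteal", "none")
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    lab <- sample(labels, n, TRUE)
    zone <- ifelse(lab == "none", NA_character_,
                   sample(c("contact", "proximal"), n, TRUE))
    dur <- sample(c(30, 60, 150, 300, 700), n, TRUE)
    ev <- make_events(1L, lab, zone, dur)
    m1 <- merge_transients(ev, p)
    m2 <- merge_transients(m1, p)
    expect_equal(as.data.frame(m2), as.data.frame(m1))
    expect_lte(nrow(m1), nrow(ev))
    expect_equal(sum(m1$duration_s), sum(ev$duration_s))
    # events still tile the span contiguously
    if (nrow(m1) > 1)
      expect_equal(m1$start_s[-1], m1$end_s[-nrow(m1)] + 10)
  }
})

test_that("duration classes split at 60 min with the boundary long", {
  p <- analysis_params()
  ev <- make_events(1L, c("vascular", "vascular", "vascular", "none"),
                    c("contact", "contact", "contact", NA),
                    c(30 * 60, 61 * 60, 60 * 60, 10 * 60))
  cl <- classify_durations(ev, p)
  expect_equal(cl$duration_class, c("short", "long", "long", NA))
})

test_that("period counting splits interactions from no-interaction", {
  ev <- make_events(1L,
                    c("vascular", "vascular", "vascular", "endosteal",
                      "endosteal", "none"),
                    c("contact", "proximal", "contact", "contact",
                      "proximal", NA),
                    rep(300, 6))
  counts <- count_periods(ev)
  expect_equal(counts$n_interaction, 5)
  expect_equal(counts$n_no_interaction, 1)
  empty <- count_periods(ev[0, ])
  expect_equal(c(empty$n_interaction, empty$n_no_interaction), c(0, 0))
  solo <- make_events(1L, "none", NA_character_, 2000)
  expect_equal(count_periods(solo)$n_no_interaction, 1)
})
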