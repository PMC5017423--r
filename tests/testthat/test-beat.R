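# Beat segmentation, frequency, direction, and alignment statistics.

test_that("beats are segmented with correct count, amplitude and timing", {
  w <- twitch_waveform(period_s = 1, rise_s = 0.2, decay_s = 0.4,
                       amplitude_um = 3)
  ds <- analytic_series(w, angle_deg = 90, duration_s = 10)
  beats <- segment_beats(ds, min_amplitude_um = 0.5, min_separation_s = 0.3)
  expect_equal(nrow(beats), 10L)
  expect_true(all(abs(beats$amp_um - 3) / 3 < 0.05))
  expect_equal(beats$t_peak_s, seq(0.2, 9.2, by = 1), tolerance = 0.03)
  expect_true(all(beats$t_start_s <= beats$t_peak_s))
  expect_true(all(beats$t_peak_s <= beats$t_end_s))
  # per-beat durations cannot exceed the recording
  expect_lte(sum(beats$duration_s), 10)
  expect_false(attr(beats, "quiescent"))
})

test_that("a flat series is quiescent and short series are rejected", {
  flat <- analytic_series(twitch_waveform(amplitude_um = 0),
                          duration_s = 4)
  beats <- segment_beats(flat)
  expect_equal(nrow(beats), 0L)
  expect_true(attr(beats, "quiescent"))
  short <- analytic_series(twitch_waveform(), duration_s = 1)
  expect_error(segment_beats(short),
               class = "pillarbeat_insufficient_data")
})

test_that("peaks closer than the separation merge into the larger beat", {
  t <- seq(0, 4, by = 0.04)
  bump <- function(c0, a, w) a * exp(-((t - c0) / w)^2)
  d <- bump(1.0, 2, 0.08) + bump(1.18, 1.5, 0.08)
  ds <- structure(data.frame(pillar_id = 1L, frame = seq_along(t),
                             time_s = t, x_px = 0, y_px = 0,
                             dx_um = d, dy_um = 0, d_um = d,
                             quality = 1, lost = FALSE),
                  class = c("displacement_series", "data.frame"))
  beats <- segment_beats(ds, min_amplitude_um = 0.5,
                         min_separation_s = 0.5)
  expect_equal(nrow(beats), 1L)
  expect_equal(beats$t_peak_s, 1.0, tolerance = 0.03)
})

test_that("beat frequency uses the median inter-peak interval", {
  w <- twitch_waveform(period_s = 1, rise_s = 0.2, decay_s = 0.4,
                       amplitude_um = 3)
  b10 <- segment_beats(analytic_series(w, duration_s = 10))
  f <- beat_frequency(b10, 10)
  expect_true(f$defined)
  expect_equal(f$freq_hz, 1.0, tolerance = 1e-6)
  expect_equal(f$rate_hz, 1.0)
  # faster pacing
  w125 <- twitch_waveform(period_s = 0.8, rise_s = 0.2, decay_s = 0.4,
                          amplitude_um = 3)
  f125 <- beat_frequency(segment_beats(analytic_series(w125,
                                                       duration_s = 10)),
                         10)
  expect_equal(f125$freq_hz, 1.25, tolerance = 0.05)
  # a single beat leaves the frequency undefined
  one <- b10[1, ]
  f1 <- beat_frequency(one, 10)
  expect_false(f1$defined)
  expect_true(is.na(f1$freq_hz))
})

test_that("beat direction follows the y-up angle convention", {
  mk <- function(dx, dy) {
    structure(data.frame(pillar_id = 1L, frame = 1:2, time_s = c(0, 0.04),
                         x_px = 0, y_px = 0,
                         dx_um = c(0, dx), dy_um = c(0, dy),
                         d_um = c(0, sqrt(dx^2 + dy^2)),
                         quality = 1, lost = FALSE),
              class = c("displacement_series", "data.frame"))
  }
  beat <- data.frame(peak_frame = 2L)
  # (0, +3 um) physical = (0, -3) image -> 90 degrees
  expect_equal(beat_direction(mk(0, -3), beat), 90)
  expect_equal(beat_direction(mk(-1, 0), beat), 180)
  expect_equal(beat_direction(mk(0, 3), beat), 270)
  expect_true(is.na(beat_direction(mk(0, 0), beat)))
})

test_that("segmented beat directions reflect the simulated axis", {
  sim <- small_fixture()
  ps <- detect_pillars(sim$stack, 16, 24)
  tr <- track_pillars(sim$stack, ps, window_px = 5)
  series <- trajectories_to_displacement(tr)
  beats <- segment_beats(series, 0.5, 0.3, k = 0.04)
  expect_true(all(abs((beats$angle_deg - 90 + 180) %% 360 - 180) < 3 |
                  abs((beats$angle_deg - 270 + 180) %% 360 - 180) < 3))
  expect_equal(beats$peak_force_un, beats$amp_um * 0.04)
})

test_that("alignment statistics separate directional and axial order", {
  all90 <- alignment_summary(rep(90, 20))
  expect_equal(all90$R, 1)
  expect_equal(all90$R2, 1)
  expect_equal(all90$dominant_axis_deg, 90)
  expect_equal(all90$circular_mean_deg, 90)
  # antipodal pairs: no directional order, perfect axial order
  anti <- alignment_summary(rep(c(90, 270), 25))
  expect_lt(anti$R, 1e-12)
  expect_equal(anti$R2, 1)
  expect_equal(anti$dominant_axis_deg, 90)
  # uniform random angles: axial order near zero (E[R2] ~ sqrt(pi/4n))
  set.seed(123)
  unif <- alignment_summary(runif(1000, 0, 360))
  expect_lt(unif$R2, 0.1)
  # histogram counts cover every vector
  expect_equal(sum(anti$counts), 50)
  expect_error(alignment_summary(numeric(0)),
               class = "pillarbeat_insufficient_data")
})

test_that("axial order is invariant to flipping any subset by 180 degrees", {
  set.seed(7)
  for (rep in 1:10) {
    ang <- runif(40, 0, 360)
    flip <- runif(40) < 0.5
    flipped <- ifelse(flip, (ang + 180) %% 360, ang)
    a <- alignment_summary(ang)
    b <- alignment_summary(flipped)
    expect_equal(b$R2, a$R2, tolerance = 1e-12)
    expect_equal(b$dominant_axis_deg, a$dominant_axis_deg,
                 tolerance = 1e-9)
  }
})

test_that("segmentation is invariant to jointly scaling series and threshold", {
  w <- twitch_waveform(period_s = 1, rise_s = 0.2, decay_s = 0.4,
                       amplitude_um = 3)
  ds <- analytic_series(w, duration_s = 6)
  b1 <- segment_beats(ds, min_amplitude_um = 0.5)
  c <- 3.7
  ds2 <- ds
  ds2$dx_um <- ds$dx_um * c; ds2$dy_um <- ds$dy_um * c
  ds2$d_um <- ds$d_um * c
  b2 <- segment_beats(ds2, min_amplitude_um = 0.5 * c)
  expect_equal(b2$peak_frame, b1$peak_frame)
  expect_equal(b2$amp_um, b1$amp_um * c, tolerance = 1e-12)
})
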