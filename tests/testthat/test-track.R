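# Sub-pixel tracking, reference estimation, displacement and force series.

test_that("noise-free tracking follows ground truth below 0.1 px RMSE", {
  sim <- small_fixture()
  ps <- detect_pillars(sim$stack, 16, 24)
  tr <- track_pillars(sim$stack, ps, window_px = 5)
  err <- tracking_errors(tr, ps, sim$truth)
  expect_lt(sqrt(mean(err^2)), 0.1)
  expect_false(any(tr$lost))
})

test_that("tracking holds below 0.3 px RMSE at SNR ~ 10", {
  sim <- small_fixture(noise_sd = 0.06)
  ps <- detect_pillars(sim$stack, 16, 24)
  tr <- track_pillars(sim$stack, ps, window_px = 5)
  err <- tracking_errors(tr, ps, sim$truth)
  expect_lt(sqrt(mean(err^2)), 0.3)
})

test_that("a static scene yields constant trajectories", {
  sim <- cached_fixture("static", function() {
    render_stack(make_lattice(2, 2, 23), twitch_waveform(amplitude_um = 0),
                 direction_field("aligned"), optics_model(),
                 n_frames = 25, seed = 4)
  })
  ps <- detect_pillars(sim$stack, 16, 24)
  tr <- track_pillars(sim$stack, ps, window_px = 5)
  for (p in split(tr, tr$pillar_id)) {
    expect_lt(diff(range(p$x_px)), 0.05)
    expect_lt(diff(range(p$y_px)), 0.05)
  }
})

test_that("tracking is invariant to a global integer-pixel translation", {
  sim <- small_fixture()
  ps <- detect_pillars(sim$stack, 16, 24)
  tr0 <- track_pillars(sim$stack, ps, window_px = 5)
  st <- shift_stack(sim$stack, 4, -3)
  ps1 <- detect_pillars(st, 16, 24)
  tr1 <- track_pillars(st, ps1, window_px = 5)
  # same per-frame displacements about the first frame, to sub-pixel level
  d0 <- tr0$x_px - ave(tr0$x_px, tr0$pillar_id, FUN = function(v) v[1])
  d1 <- tr1$x_px - ave(tr1$x_px, tr1$pillar_id, FUN = function(v) v[1])
  expect_equal(sort(d1), sort(d0), tolerance = 0.02)
})

test_that("reference estimation finds the relaxed position", {
  sim <- small_fixture()
  ps <- detect_pillars(sim$stack, 16, 24)
  tr <- track_pillars(sim$stack, ps, window_px = 5)
  map <- match_truth(ps, sim$truth)
  for (i in c(1, 5, 9)) {
    one <- tr[tr$pillar_id == ps$pillar_id[i], ]
    ref <- estimate_reference(one)
    expect_equal(ref$x_px, sim$truth$pillars$rest_x_px[map[i]],
                 tolerance = 0.1)
    expect_equal(ref$y_px, sim$truth$pillars$rest_y_px[map[i]],
                 tolerance = 0.1)
  }
  # constant trajectory: the reference is that constant
  const <- data.frame(frame = 1:20, x_px = rep(7.25, 20),
                      y_px = rep(3.5, 20), lost = FALSE)
  refc <- estimate_reference(const)
  expect_equal(c(refc$x_px, refc$y_px), c(7.25, 3.5))
  expect_error(estimate_reference(const[1:5, ]),
               class = "pillarbeat_insufficient_data")
})

test_that("rolling baseline tolerates drift where a fixed frame does not", {
  w <- twitch_waveform(period_s = 1, rise_s = 0.2, decay_s = 0.4,
                       amplitude_um = 3)
  fps <- 25
  t <- seq(0, 10 - 1 / fps, by = 1 / fps)
  s_px <- twitch_displacement(w, t) / 0.5
  drift <- 0.15 * t # px/s, slow stage drift along x
  traj <- data.frame(frame = seq_along(t),
                     x_px = 100 + drift,
                     y_px = 80 - s_px, # beating upward (90 deg)
                     lost = FALSE)
  roll <- estimate_reference(traj, method = "rolling", window_frames = 50)
  true_rest_x <- 100 + drift
  err_roll <- abs(roll$x_px - true_rest_x)
  expect_lt(median(err_roll), 0.2)
  fixed <- estimate_reference(traj, method = "fixed", frame = 1L)
  err_fixed <- abs(fixed$x_px - true_rest_x)
  expect_gt(max(err_fixed), 1) # end-of-record drift left uncorrected
})

test_that("displacement conversion is exact and linear in pixel size", {
  traj <- data.frame(pillar_id = 1L, frame = 1:3,
                     x_px = c(10, 14, 10), y_px = c(20, 23, 20),
                     quality = 1, lost = FALSE)
  ref <- list(x_px = 10, y_px = 20, method = "fixed")
  ds <- to_displacement(traj, ref, pixel_size_um = 0.5,
                        frame_rate_fps = 25)
  expect_equal(ds$dx_um, c(0, 2, 0))
  expect_equal(ds$dy_um, c(0, 1.5, 0))
  expect_equal(ds$d_um, c(0, 2.5, 0))
  expect_equal(ds$time_s, (0:2) / 25)
  # zero at the reference by construction
  expect_equal(ds$d_um[1], 0)
  # exactly linear in pixel size
  ds2 <- to_displacement(traj, ref, pixel_size_um = 1.7,
                         frame_rate_fps = 25)
  expect_equal(ds2$dx_um, ds$dx_um * (1.7 / 0.5), tolerance = 1e-12)
  expect_error(to_displacement(traj, ref, pixel_size_um = 0),
               class = "pillarbeat_error")
})

test_that("force series delegate to the spring relation framewise", {
  w <- twitch_waveform(amplitude_um = 3.0071)
  ds <- analytic_series(w, angle_deg = 90, duration_s = 4)
  fs <- to_force(ds, 0.04)
  expect_identical(trunc(max(fs$force_un) * 1e4) / 1e4, 0.1202)
  expect_equal(fs$force_un, ds$d_um * 0.04)
  fs2 <- to_force(ds, 0.08)
  expect_equal(fs2$force_un, 2 * fs$force_un, tolerance = 1e-12)
  zero <- analytic_series(twitch_waveform(amplitude_um = 0),
                          duration_s = 4)
  expect_true(all(to_force(zero, 0.04)$force_un == 0))
})

test_that("pipeline recovers waveform amplitude and direction end to end", {
  sim <- small_fixture()
  ps <- detect_pillars(sim$stack, 16, 24)
  tr <- track_pillars(sim$stack, ps, window_px = 5)
  series <- trajectories_to_displacement(tr)
  w <- sim$truth$waveform
  map <- match_truth(ps, sim$truth)
  for (i in seq_len(nrow(ps))) {
    sd <- series[series$pillar_id == ps$pillar_id[i], ]
    expect_equal(max(sd$d_um), w$amplitude_um, tolerance = 0.05 * 3)
    pk <- which.max(sd$d_um)
    ang <- (atan2(-sd$dy_um[pk], sd$dx_um[pk]) * 180 / pi) %% 360
    truth_ang <- sim$truth$pillars$true_angle_deg[map[i]]
    expect_lt(abs((ang - truth_ang + 180) %% 360 - 180), 3)
  }
})
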