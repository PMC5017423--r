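# Synthetic stack generator: lattice, twitch waveform, rendering contract.

test_that("make_lattice places centres on a row-major square grid", {
  l <- make_lattice(2, 2, 23)
  expect_equal(l$x_um, c(0, 23, 0, 23))
  expect_equal(l$y_um, c(0, 0, 23, 23))
  l1 <- make_lattice(1, 1, 10, origin_um = c(5, 5))
  expect_equal(nrow(l1), 1L)
  expect_equal(c(l1$x_um, l1$y_um), c(5, 5))
  l2 <- make_lattice(3, 4, 10)
  expect_equal(nrow(l2), 12L)
  expect_equal(max(l2$x_um), 30)
  expect_equal(max(l2$y_um), 20)
  expect_error(make_lattice(0, 2, 23), class = "pillarbeat_error")
})

test_that("twitch waveform starts at rest, peaks at amplitude, is periodic", {
  w <- twitch_waveform(period_s = 1, rise_s = 0.2, decay_s = 0.4,
                       amplitude_um = 3)
  expect_equal(twitch_displacement(w, 0), 0)
  expect_equal(twitch_displacement(w, 0.2), 3) # end of rise = peak
  expect_equal(twitch_displacement(w, 0.6), 0, tolerance = 1e-12)
  t <- seq(0, 0.99, by = 0.01)
  expect_equal(twitch_displacement(w, t), twitch_displacement(w, t + 1))
  expect_true(all(twitch_displacement(w, t) <= 3 + 1e-12))
  expect_error(twitch_waveform(period_s = 0.5, rise_s = 0.3, decay_s = 0.3),
               class = "pillarbeat_error")
})

test_that("rendering is bit-identical under a fixed seed", {
  a <- default_fixture(noise_sd = 0.05, seed = 11, duration_s = 1,
                       rows = 2, cols = 2)
  b <- default_fixture(noise_sd = 0.05, seed = 11, duration_s = 1,
                       rows = 2, cols = 2)
  c <- default_fixture(noise_sd = 0.05, seed = 12, duration_s = 1,
                       rows = 2, cols = 2)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_false(identical(a$stack$frames, c$stack$frames))
  # the caller's RNG state is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(default_fixture(noise_sd = 0.05, seed = 5,
                                          duration_s = 0.2,
                                          rows = 1, cols = 1))
  expect_identical(runif(3), before)
})

test_that("ground truth obeys the waveform contract", {
  sim <- small_fixture()
  tp <- sim$truth$positions
  w <- sim$truth$waveform
  # starts at rest
  expect_equal(tp$true_d_um[tp$frame == 1], rep(0, 9))
  # magnitudes never exceed amplitude + |baseline|
  expect_true(all(tp$true_d_um <= w$amplitude_um +
                    abs(w$baseline_um) + 1e-12))
  # peak pixel displacement equals amplitude / pixel size
  px <- sim$truth$optics$pixel_size_um
  one <- tp[tp$pillar_id == 1, ]
  rest <- sim$truth$pillars[1, ]
  disp_px <- sqrt((one$true_x_px - rest$rest_x_px)^2 +
                  (one$true_y_px - rest$rest_y_px)^2)
  expect_equal(max(disp_px), w$amplitude_um / px, tolerance = 1e-9)
  # aligned field with zero jitter: all true angles at the axis
  expect_equal(sim$truth$pillars$true_angle_deg, rep(90, 9))
})

test_that("a static noise-free scene renders identical frames", {
  sim <- render_stack(make_lattice(2, 2, 23),
                      twitch_waveform(amplitude_um = 0),
                      direction_field("aligned"),
                      optics_model(noise_sd = 0),
                      n_frames = 5, seed = 3)
  for (f in 2:5) expect_identical(sim$stack$frames[[f]],
                                  sim$stack$frames[[1]])
})

test_that("mean frame intensity is monotone in signal level", {
  mean_at <- function(sig) {
    sim <- render_stack(make_lattice(2, 2, 23),
                        twitch_waveform(amplitude_um = 0),
                        direction_field("aligned"),
                        optics_model(signal_level = sig, noise_sd = 0.02),
                        n_frames = 2, seed = 21)
    mean(sim$stack$frames[[1]])
  }
  m <- vapply(c(0.2, 0.4, 0.6), mean_at, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("overlapping pillar tops are refused", {
  expect_error(
    render_stack(make_lattice(2, 2, pitch_um = 10), # 20 px < 2 x 16 px
                 twitch_waveform(), direction_field("aligned"),
                 optics_model(), n_frames = 2, seed = 1),
    class = "pillarbeat_geometry_error")
})

test_that("isotropic direction fields draw per-pillar uniform angles", {
  sim <- render_stack(make_lattice(3, 3, 23), twitch_waveform(),
                      direction_field("isotropic"),
                      optics_model(), n_frames = 2, seed = 8)
  ang <- sim$truth$pillars$true_angle_deg
  expect_true(all(ang >= 0 & ang < 360))
  expect_gt(length(unique(round(ang, 3))), 5)
})

test_that("write_simulation emits TIFF + truth CSV + params JSON", {
  sim <- render_stack(make_lattice(2, 2, 23), twitch_waveform(),
                      direction_field("aligned"), optics_model(),
                      n_frames = 3, seed = 2)
  out <- file.path(tempdir(), "sim_test.tif")
  paths <- write_simulation(sim, out)
  expect_true(all(file.exists(paths)))
  truth <- read.csv(paths["truth"])
  expect_equal(nrow(truth), 4 * 3)
  expect_named(truth, c("pillar_id", "frame", "true_x_um", "true_y_um",
                        "true_angle_deg"))
  params <- jsonlite::read_json(paths["params"])
  expect_equal(params$seed, 2)
  unlink(paths)
})
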