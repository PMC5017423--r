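# Shared fixtures, built in code and cached for the duration of the test
# session (rendering is deterministic, so caching cannot leak state).

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 3x3 lattice, 4 s: the workhorse small scene.
small_fixture <- function(noise_sd = 0, seed = 1) {
  cached_fixture(sprintf("small_%g_%d", noise_sd, seed), function() {
    default_fixture(noise_sd = noise_sd, seed = seed, duration_s = 4,
                    rows = 3, cols = 3)
  })
}

# Match detected pillars to ground-truth pillars by resting centre.
match_truth <- function(pillars, truth) {
  vapply(seq_len(nrow(pillars)), function(i) {
    which.min((truth$pillars$rest_x_px - pillars$x_px[i])^2 +
              (truth$pillars$rest_y_px - pillars$y_px[i])^2)
  }, integer(1))
}

# Per-frame tracking error (px) of trajectories against ground truth.
tracking_errors <- function(trajectories, pillars, truth) {
  map <- match_truth(pillars, truth)
  unlist(lapply(seq_len(nrow(pillars)), function(i) {
    tr <- trajectories[trajectories$pillar_id == pillars$pillar_id[i], ]
    tr <- tr[order(tr$frame), ]
    tp <- truth$positions[truth$positions$pillar_id == map[i], ]
    tp <- tp[order(tp$frame), ]
    sqrt((tr$x_px - tp$true_x_px)^2 + (tr$y_px - tp$true_y_px)^2)
  }))
}

# Shift every frame of a stack by an integer pixel offset (content moves by
# +dx right, +dy down), filling the vacated border with the frame's median.
shift_stack <- function(stack, dx, dy) {
  shifted <- lapply(stack$frames, function(f) {
    H <- nrow(f); W <- ncol(f)
    out <- matrix(median(f), H, W)
    src_r <- seq_len(H) - dy
    src_c <- seq_len(W) - dx
    ok_r <- src_r >= 1 & src_r <= H
    ok_c <- src_c >= 1 & src_c <= W
    out[ok_r, ok_c] <- f[src_r[ok_r], src_c[ok_c]]
    out
  })
  image_stack(shifted, stack$pixel_size_um, stack$frame_rate_fps)
}

# Build a displacement series analytically from a twitch waveform and a
# physical direction, bypassing rendering and tracking.
analytic_series <- function(waveform, angle_deg = 90, fps = 25,
                            duration_s = 10, pillar_id = 1L) {
  t <- seq(0, duration_s - 1 / fps, by = 1 / fps)
  s <- twitch_displacement(waveform, t)
  th <- angle_deg * pi / 180
  dx <- s * cos(th)
  dy <- -s * sin(th) # image frame, y down
  structure(data.frame(pillar_id = pillar_id, frame = seq_along(t),
                       time_s = t, x_px = dx / 0.5, y_px = dy / 0.5,
                       dx_um = dx, dy_um = dy, d_um = abs(s),
                       quality = 1, lost = FALSE),
            class = c("displacement_series", "data.frame"),
            pixel_size_um = 0.5, frame_rate_fps = fps)
}
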