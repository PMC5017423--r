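# Sub-pixel template tracking of pillar tops and conversion to calibrated
# deflection/force time series.
#
# Each pillar's template is cut once from the reference frame (pillar
# appearance is static, so no drift-prone template updating). In every frame
# the template is matched by normalized cross-correlation over an integer
# shift grid centred on the previous frame's position, and the correlation
# peak is localized to sub-pixel precision by separable parabolic
# interpolation. Frames whose peak correlation falls below the quality
# threshold are flagged `lost` and filled by linear interpolation, never
# silently dropped.

# Precompute the gather matrix mapping a (K + 2*sr)^2 search region to the
# K^2 x (2*sr+1)^2 matrix of all shifted K x K patches.
shift_index_matrix <- function(K, sr) {
  R <- K + 2L * sr
  base <- as.vector(outer(seq_len(K), (seq_len(K) - 1L) * R, "+"))
  shifts <- expand.grid(dr = 0:(2L * sr), dc = 0:(2L * sr))
  idx <- outer(base, shifts$dr + shifts$dc * R, "+")
  list(idx = idx, shifts = shifts, R = R)
}

# Parabolic sub-pixel offset from three samples around a peak.
parabolic_offset <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (cm - cp) / den
  max(min(off, 0.5), -0.5)
}

#' Track pillar tops through a stack
#'
#' @param stack An [image_stack()].
#' @param pillars A `pillar_set` from [detect_pillars()] or
#'   [accept_manual_seeds()].
#' @param window_px Search half-width in pixels around the position
#'   predicted from the previous frame; must comfortably exceed the
#'   frame-to-frame motion.
#' @param template_radius_px Template half-width; default covers the pillar
#'   top plus a 2 px rim.
#' @param reference_frame Index of the frame templates are cut from;
#'   defaults to the `pillar_set`'s reference frame or 1.
#' @param quality_threshold Minimum peak correlation; below it a frame is
#'   flagged lost.
#' @return A `trajectories` data.frame: `pillar_id, frame, time_s, x_px,
#'   y_px, quality, lost`, with `pixel_size_um` and `frame_rate_fps`
#'   attributes.
#' @export
track_pillars <- function(stack, pillars, window_px = 5,
                          template_radius_px = NULL,
                          reference_frame = NULL,
                          quality_threshold = 0.5) {
  if (nrow(pillars) == 0L) {
    pb_stop("empty pillar set", "pillarbeat_invalid_parameter")
  }
  if (is.null(reference_frame)) {
    reference_frame <- attr(pillars, "reference_frame")
    if (is.null(reference_frame) || is.na(reference_frame)) {
      reference_frame <- 1L
    }
  }
  if (is.null(template_radius_px)) {
    template_radius_px <- ceiling(max(pillars$radius_px) + 2)
  }
  th <- as.integer(template_radius_px)
  sr <- as.integer(ceiling(window_px))
  K <- 2L * th + 1L
  gather <- shift_index_matrix(K, sr)
  S <- 2L * sr + 1L

  ref <- stack$frames[[reference_frame]]
  H <- nrow(ref); W <- ncol(ref)
  n_f <- length(stack$frames)
  n_p <- nrow(pillars)

  x_out <- matrix(NA_real_, n_f, n_p)
  y_out <- matrix(NA_real_, n_f, n_p)
  q_out <- matrix(NA_real_, n_f, n_p)

  for (p in seq_len(n_p)) {
    cx <- pillars$x_px[p]; cy <- pillars$y_px[p]
    r0 <- round(cy) + 1L # template anchor, 1-based matrix indices
    c0 <- round(cx) + 1L
    if (r0 - th < 1L || r0 + th > H || c0 - th < 1L || c0 + th > W) {
      pb_warn(sprintf("pillar %s too close to the border; skipped",
                      pillars$pillar_id[p]), "pillarbeat_border_pillar")
      next
    }
    tmpl <- ref[(r0 - th):(r0 + th), (c0 - th):(c0 + th)]
    tc <- as.vector(tmpl) - mean(tmpl)
    tss <- sum(tc^2)
    if (tss <= 0) next

    off_r <- 0L; off_c <- 0L # integer offset carried frame to frame
    for (f in seq_len(n_f)) {
      rs <- r0 + off_r - th - sr
      cs <- c0 + off_c - th - sr
      if (rs < 1L || cs < 1L || rs + gather$R - 1L > H ||
          cs + gather$R - 1L > W) {
        q_out[f, p] <- 0 # search region leaves the image
        next
      }
      region <- stack$frames[[f]][rs:(rs + gather$R - 1L),
                                  cs:(cs + gather$R - 1L)]
      P <- matrix(region[gather$idx], nrow = K * K)
      pm <- colMeans(P)
      pss <- colSums(P * P) - (K * K) * pm^2
      ncc <- as.vector(crossprod(tc, P)) / sqrt(tss * pmax(pss, 1e-12))
      ncc[pss <= 1e-12] <- -1
      best <- which.max(ncc)
      nm <- matrix(ncc, S, S) # rows = dr, cols = dc
      br <- (best - 1L) %% S + 1L
      bc <- (best - 1L) %/% S + 1L
      sub_r <- if (br > 1L && br < S)
        parabolic_offset(nm[br - 1L, bc], nm[br, bc], nm[br + 1L, bc]) else 0
      sub_c <- if (bc > 1L && bc < S)
        parabolic_offset(nm[br, bc - 1L], nm[br, bc], nm[br, bc + 1L]) else 0
      dr <- off_r + (br - 1L - sr)
      dc <- off_c + (bc - 1L - sr)
      x_out[f, p] <- cx + dc + sub_c
      y_out[f, p] <- cy + dr + sub_r
      q_out[f, p] <- nm[br, bc]
      off_r <- dr; off_c <- dc
    }
  }

  lost <- q_out < quality_threshold | !is.finite(q_out)
  # fill lost frames by linear interpolation along time, flagged not dropped
  for (p in seq_len(n_p)) {
    bad <- lost[, p]
    if (all(bad)) next
    if (any(bad)) {
      ok <- which(!bad)
      x_out[bad, p] <- approx(ok, x_out[ok, p], xout = which(bad),
                              rule = 2)$y
      y_out[bad, p] <- approx(ok, y_out[ok, p], xout = which(bad),
                              rule = 2)$y
    }
  }

  out <- data.frame(
    pillar_id = rep(pillars$pillar_id, each = n_f),
    frame = rep(seq_len(n_f), n_p),
    time_s = rep((seq_len(n_f) - 1L) / stack$frame_rate_fps, n_p),
    x_px = as.vector(x_out),
    y_px = as.vector(y_out),
    quality = as.vector(q_out),
    lost = as.vector(lost)
  )
  structure(out, class = c("trajectories", "data.frame"),
            pixel_size_um = stack$pixel_size_um,
            frame_rate_fps = stack$frame_rate_fps,
            reference_frame = reference_frame)
}

#' Estimate a pillar's relaxed reference position
#'
#' The reference position is the pillar's position between contractions.
#' The default `"percentile"` method projects the trajectory onto its
#' principal motion axis (oriented so that contraction excursions are
#' positive), and averages the frames at or below the 10th percentile of
#' that projection — the relaxed extreme. `"fixed"` uses a given frame's
#' position (the original position). `"rolling"` computes a per-frame
#' baseline from a rolling window, tolerant of slow drift.
#'
#' @param trajectory A single pillar's rows of a `trajectories` data.frame
#'   (columns `frame, x_px, y_px, lost`), >= 10 frames.
#' @param method `"percentile"`, `"fixed"`, or `"rolling"`.
#' @param probs Percentile for the relaxed extreme (default 0.1).
#' @param frame Frame index for `"fixed"`.
#' @param window_frames Rolling window width (default: 3 s worth if the
#'   frame rate is attached, else 75).
#' @return A list: `x_px`, `y_px` (scalars, or per-frame vectors for
#'   `"rolling"`), and `method`.
#' @export
estimate_reference <- function(trajectory,
                               method = c("percentile", "fixed", "rolling"),
                               probs = 0.1, frame = 1L,
                               window_frames = NULL) {
  method <- match.arg(method)
  n <- nrow(trajectory)
  if (n < 10L) {
    pb_stop("reference estimation needs >= 10 frames",
            "pillarbeat_insufficient_data")
  }
  ok <- if ("lost" %in% names(trajectory)) !trajectory$lost else rep(TRUE, n)
  if (!any(ok)) {
    pb_stop("all frames lost; cannot estimate reference",
            "pillarbeat_insufficient_data")
  }
  X <- cbind(trajectory$x_px, trajectory$y_px)

  if (method == "fixed") {
    return(list(x_px = X[frame, 1], y_px = X[frame, 2], method = method))
  }

  ctr <- colMeans(X[ok, , drop = FALSE])
  Xc <- sweep(X, 2, ctr)
  if (max(abs(Xc[ok, ])) < 1e-12) {
    # constant trajectory: the reference is that constant
    if (method == "rolling") {
      return(list(x_px = X[, 1], y_px = X[, 2], method = method))
    }
    return(list(x_px = ctr[1], y_px = ctr[2], method = method))
  }
  v <- svd(Xc[ok, , drop = FALSE])$v[, 1]
  proj <- Xc %*% v
  if (mean(proj[ok]^3) < 0) { # orient: excursions (contractions) positive
    v <- -v
    proj <- -proj
  }
  u <- c(-v[2], v[1]) # orthogonal axis
  orth <- Xc %*% u

  if (method == "percentile") {
    q <- quantile(proj[ok], probs)
    sel <- ok & proj <= q
    ref <- colMeans(X[sel, , drop = FALSE])
    return(list(x_px = unname(ref[1]), y_px = unname(ref[2]),
                method = method))
  }

  # rolling: per-frame low-percentile baseline along the motion axis and a
  # rolling median across it
  if (is.null(window_frames)) window_frames <- 75L
  hw <- max(5L, window_frames %/% 2L)
  base_p <- numeric(n); base_o <- numeric(n)
  for (i in seq_len(n)) {
    w <- max(1L, i - hw):min(n, i + hw)
    w <- w[ok[w]]
    base_p[i] <- quantile(proj[w], probs)
    base_o[i] <- median(orth[w])
  }
  list(x_px = ctr[1] + base_p * v[1] + base_o * u[1],
       y_px = ctr[2] + base_p * v[2] + base_o * u[2],
       method = method)
}

#' Convert a trajectory to a calibrated displacement series
#'
#' Deflection is position minus reference, scaled by the pixel size:
#' `dx_um = (x_px - xref) * pixel_size_um` and likewise for y; the
#' magnitude is the Euclidean norm. The deflection at the reference
#' position is 0 by construction.
#'
#' @param trajectory A single pillar's rows of a `trajectories` data.frame.
#' @param reference A list from [estimate_reference()] (scalar or per-frame
#'   reference).
#' @param pixel_size_um Microns per pixel (> 0).
#' @param frame_rate_fps Frames per second, used for the `time_s` column if
#'   the trajectory lacks one.
#' @return A `displacement_series` data.frame: `pillar_id, frame, time_s,
#'   x_px, y_px, dx_um, dy_um, d_um, quality, lost`, with the reference and
#'   pixel size as attributes.
#' @export
to_displacement <- function(trajectory, reference, pixel_size_um,
                            frame_rate_fps = NULL) {
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  dx <- (trajectory$x_px - reference$x_px) * pixel_size_um
  dy <- (trajectory$y_px - reference$y_px) * pixel_size_um
  if (is.null(frame_rate_fps)) frame_rate_fps <- attr(trajectory, "frame_rate_fps")
  time_s <- if ("time_s" %in% names(trajectory)) trajectory$time_s
            else (trajectory$frame - 1L) / frame_rate_fps
  out <- data.frame(
    pillar_id = if ("pillar_id" %in% names(trajectory))
      trajectory$pillar_id else 1L,
    frame = trajectory$frame,
    time_s = time_s,
    x_px = trajectory$x_px, y_px = trajectory$y_px,
    dx_um = dx, dy_um = dy,
    d_um = sqrt(dx^2 + dy^2),
    quality = if ("quality" %in% names(trajectory))
      trajectory$quality else NA_real_,
    lost = if ("lost" %in% names(trajectory)) trajectory$lost else FALSE
  )
  structure(out, class = c("displacement_series", "data.frame"),
            pixel_size_um = pixel_size_um,
            frame_rate_fps = frame_rate_fps,
            reference = reference)
}

#' Convert tracked trajectories to displacement series for all pillars
#'
#' Convenience wrapper: estimates each pillar's reference and stacks the
#' per-pillar [to_displacement()] results.
#'
#' @param trajectories A `trajectories` data.frame from [track_pillars()].
#' @param pixel_size_um Microns per pixel; defaults to the attribute set by
#'   [track_pillars()].
#' @param method Reference method passed to [estimate_reference()].
#' @return A `displacement_series` data.frame covering all pillars.
#' @export
trajectories_to_displacement <- function(trajectories, pixel_size_um = NULL,
                                         method = "percentile") {
  if (is.null(pixel_size_um)) {
    pixel_size_um <- attr(trajectories, "pixel_size_um")
  }
  fps <- attr(trajectories, "frame_rate_fps")
  parts <- lapply(split(trajectories, trajectories$pillar_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (all(!is.finite(tr$x_px))) return(NULL)
    ref <- estimate_reference(tr, method = method)
    to_displacement(tr, ref, pixel_size_um, frame_rate_fps = fps)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  structure(out, class = c("displacement_series", "data.frame"),
            pixel_size_um = pixel_size_um, frame_rate_fps = fps,
            reference_method = method)
}

#' Convert a displacement series to force
#'
#' Applies the linear spring relation framewise: `force_un = d_um * k` (and
#' componentwise `fx_un`, `fy_un`).
#'
#' @param series A `displacement_series` data.frame.
#' @param k A [spring_constant()] or stiffness in N/m.
#' @return The series with `fx_un`, `fy_un`, `force_un` columns added.
#' @export
to_force <- function(series, k) {
  kv <- resolve_k(k)
  series$fx_un <- force_from_deflection(series$dx_um, kv)
  series$fy_un <- force_from_deflection(series$dy_um, kv)
  series$force_un <- series$d_um * kv
  series
}
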