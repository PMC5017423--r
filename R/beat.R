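# Beat segmentation and contraction-direction statistics.
#
# A beat is one contraction event: a peak of the deflection magnitude d(t)
# with prominence above the detection threshold, bounded by the nearest
# sub-threshold crossings. Prominence rather than absolute height drives
# the peak test so that slow baseline drift does not mask beats.
# Direction statistics are reported both directionally (resultant length R)
# and axially (R2, on doubled angles): groove-aligned cardiomyocytes beat
# back and forth along one axis, so opposite directions such as 90 and 270
# degrees are the same alignment.

# Indices of strict-or-plateau local maxima of a numeric vector.
find_local_maxima <- function(d) {
  n <- length(d)
  if (n < 3L) return(integer(0))
  which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
}

# Topographic prominence of each peak.
peak_prominence <- function(d, peaks) {
  vapply(peaks, function(p) {
    h <- d[p]
    left <- if (p > 1) {
      i <- (p - 1):1
      higher <- which(d[i] > h)
      seg <- if (length(higher)) i[1:(higher[1])] else i
      min(d[seg])
    } else h
    right <- if (p < length(d)) {
      i <- (p + 1):length(d)
      higher <- which(d[i] > h)
      seg <- if (length(higher)) i[1:(higher[1])] else i
      min(d[seg])
    } else h
    h - max(left, right)
  }, numeric(1))
}

segment_beats_one <- function(sd, min_amplitude_um, min_separation_s, k) {
  d <- sd$d_um
  t <- sd$time_s
  pk <- find_local_maxima(d)
  pk <- pk[d[pk] >= min_amplitude_um]
  if (length(pk)) {
    prom <- peak_prominence(d, pk)
    pk <- pk[prom >= min_amplitude_um]
  }
  # enforce minimum separation, keeping the taller peak of close pairs
  if (length(pk) > 1L) {
    o <- pk[order(d[pk], decreasing = TRUE)]
    kept <- integer(0)
    for (p in o) {
      if (!length(kept) || all(abs(t[p] - t[kept]) >= min_separation_s)) {
        kept <- c(kept, p)
      }
    }
    pk <- sort(kept)
  }
  if (!length(pk)) {
    out <- data.frame(pillar_id = integer(0), beat_index = integer(0),
                      start_frame = integer(0), peak_frame = integer(0),
                      end_frame = integer(0), t_start_s = numeric(0),
                      t_peak_s = numeric(0), t_end_s = numeric(0),
                      amp_um = numeric(0), peak_force_un = numeric(0),
                      angle_deg = numeric(0), duration_s = numeric(0))
    attr(out, "quiescent") <- TRUE
    return(out)
  }
  n <- length(d)
  below <- d < min_amplitude_um
  bounds <- t(vapply(pk, function(p) {
    lo <- which(below[1:p])
    s <- if (length(lo)) max(lo) else 1L
    hi <- which(below[p:n])
    e <- if (length(hi)) p + min(hi) - 1L else n
    c(s, e)
  }, integer(2)))
  amp <- vapply(seq_along(pk), function(i) {
    max(d[bounds[i, 1]:bounds[i, 2]])
  }, numeric(1))
  ang <- angle_from_image_vec(sd$dx_um[pk], sd$dy_um[pk])
  ang[sd$d_um[pk] <= 0] <- NA_real_
  out <- data.frame(
    pillar_id = sd$pillar_id[1],
    beat_index = seq_along(pk),
    start_frame = sd$frame[bounds[, 1]],
    peak_frame = sd$frame[pk],
    end_frame = sd$frame[bounds[, 2]],
    t_start_s = t[bounds[, 1]],
    t_peak_s = t[pk],
    t_end_s = t[bounds[, 2]],
    amp_um = amp,
    peak_force_un = if (is.null(k)) NA_real_ else amp * resolve_k(k),
    angle_deg = ang,
    duration_s = t[bounds[, 2]] - t[bounds[, 1]]
  )
  attr(out, "quiescent") <- FALSE
  out
}

#' Segment contraction beats from a displacement series
#'
#' Peaks of the deflection magnitude with height and prominence at least
#' `min_amplitude_um` and pairwise spacing at least `min_separation_s`;
#' beat boundaries sit at the nearest preceding/following crossings below
#' `min_amplitude_um`. Deterministic. A series with no qualifying peaks
#' returns an empty table carrying a `quiescent` attribute.
#'
#' @param series A `displacement_series` data.frame (one or more pillars,
#'   >= 2 s of data per pillar).
#' @param min_amplitude_um Detection threshold in micrometres.
#' @param min_separation_s Minimum peak spacing in seconds.
#' @param k Optional [spring_constant()] (or N/m value); when given, each
#'   beat's `peak_force_un` is filled via the linear spring relation.
#' @return A `beats` data.frame: `pillar_id, beat_index, start_frame,
#'   peak_frame, end_frame, t_start_s, t_peak_s, t_end_s, amp_um,
#'   peak_force_un, angle_deg, duration_s`.
#' @export
segment_beats <- function(series, min_amplitude_um = 0.5,
                          min_separation_s = 0.3, k = NULL) {
  check_positive_scalar(min_amplitude_um, "min_amplitude_um")
  check_positive_scalar(min_separation_s, "min_separation_s")
  per <- lapply(split(series, series$pillar_id), function(sd) {
    sd <- sd[order(sd$frame), ]
    if (diff(range(sd$time_s)) < 2) {
      pb_stop("beat segmentation needs >= 2 s of data",
              "pillarbeat_insufficient_data")
    }
    segment_beats_one(sd, min_amplitude_um, min_separation_s, k)
  })
  out <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  attr(out, "quiescent") <- all(vapply(per, attr, logical(1), "quiescent"))
  class(out) <- c("beats", "data.frame")
  out
}

#' Beating frequency from segmented beats
#'
#' Primary estimate: the reciprocal of the median inter-peak interval,
#' robust to a missed or extra beat; the plain count/duration rate is also
#' reported. Fewer than two beats leave the frequency undefined.
#'
#' @param beats A `beats` data.frame (a single pillar, or pooled peak
#'   times).
#' @param duration_s Recording duration in seconds.
#' @return A list: `freq_hz` (NA if undefined), `rate_hz`
#'   (count/duration), `n_beats`, `defined` (logical).
#' @export
beat_frequency <- function(beats, duration_s) {
  tp <- sort(beats$t_peak_s)
  n <- length(tp)
  if (n < 2L) {
    return(list(freq_hz = NA_real_, rate_hz = n / duration_s,
                n_beats = n, defined = FALSE))
  }
  list(freq_hz = 1 / median(diff(tp)), rate_hz = n / duration_s,
       n_beats = n, defined = TRUE)
}

#' Contraction direction of one beat
#'
#' The direction of the deflection vector at the beat's peak frame, in the
#' package's physical y-up convention, mapped to `[0, 360)`. A zero vector
#' at the peak leaves the direction undefined (NA).
#'
#' @param series The pillar's `displacement_series` data.frame.
#' @param beat One row of a `beats` data.frame for the same pillar.
#' @return Angle in degrees, or NA for a zero peak vector.
#' @export
beat_direction <- function(series, beat) {
  row <- series[series$frame == beat$peak_frame, ]
  if (nrow(row) == 0L) {
    pb_stop("beat peak frame not present in series",
            "pillarbeat_invalid_parameter")
  }
  dx <- row$dx_um[1]; dy <- row$dy_um[1]
  if (sqrt(dx^2 + dy^2) <= 0) return(NA_real_)
  angle_from_image_vec(dx, dy)
}

#' Directional and axial alignment statistics
#'
#' For beat direction angles \eqn{\theta_i} (degrees):
#' the directional resultant length \eqn{R = |mean(e^{i\theta})|} with its
#' circular mean, and the axial order parameter
#' \eqn{R_2 = |mean(e^{i 2\theta})|} with the dominant axis
#' \eqn{\frac{1}{2} arg(mean(e^{i 2\theta}))}. Axial statistics treat
#' opposite directions as one orientation, which is the right notion of
#' groove alignment: a pillar beating back and forth along 90/270 degrees
#' has R near 0 but R2 = 1 with axis 90.
#'
#' @param angles_deg Angles in degrees (>= 1, NAs dropped).
#' @param n_bins Number of equal histogram bins over `[0, 360)`.
#' @return An `alignment_summary` list: `n`, `circular_mean_deg`, `R`,
#'   `R2`, `dominant_axis_deg` (in `[0, 180)`), `bin_edges_deg`, `counts`.
#' @export
alignment_summary <- function(angles_deg, n_bins = 36) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (length(angles_deg) == 0L) {
    pb_stop("alignment summary needs at least one angle",
            "pillarbeat_insufficient_data")
  }
  th <- angles_deg * pi / 180
  z1 <- complex(real = mean(cos(th)), imaginary = mean(sin(th)))
  z2 <- complex(real = mean(cos(2 * th)), imaginary = mean(sin(2 * th)))
  edges <- seq(0, 360, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(angles_deg %% 360, edges,
                                  rightmost.closed = TRUE), n_bins)
  structure(list(
    n = length(angles_deg),
    circular_mean_deg = (Arg(z1) * 180 / pi) %% 360,
    R = Mod(z1),
    R2 = Mod(z2),
    dominant_axis_deg = ((Arg(z2) / 2) * 180 / pi) %% 180,
    bin_edges_deg = edges,
    counts = counts
  ), class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Alignment of %d beat vectors: R = %.3f ",
           "(circular mean %.1f deg), axial R2 = %.3f, axis %.1f deg\n"),
    x$n, x$R, x$circular_mean_deg, x$R2, x$dominant_axis_deg))
  invisible(x)
}

#' Rose (angular histogram) plot of beat directions
#'
#' @param x An `alignment_summary`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.alignment_summary <- function(x, ...) {
  mx <- max(x$counts, 1)
  plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
       xlab = "", ylab = "",
       main = sprintf("Beat directions (R2 = %.2f, axis %.0f deg)",
                      x$R2, x$dominant_axis_deg), ...)
  phi <- seq(0, 2 * pi, length.out = 181)
  lines(cos(phi), sin(phi), col = "grey70")
  for (i in seq_along(x$counts)) {
    if (x$counts[i] == 0) next
    a0 <- x$bin_edges_deg[i] * pi / 180
    a1 <- x$bin_edges_deg[i + 1] * pi / 180
    r <- x$counts[i] / mx
    aa <- seq(a0, a1, length.out = 8)
    polygon(c(0, r * cos(aa)), c(0, r * sin(aa)), col = "steelblue",
            border = "white")
  }
  invisible(x)
}
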