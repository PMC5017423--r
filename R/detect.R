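# Pillar-top detection in a reference frame.
#
# Bright-blob detection: difference-of-Gaussians band-pass (which also
# removes slowly varying background), strict local maxima, greedy
# non-maximum suppression at the requested separation, then sub-pixel
# refinement by intensity-weighted centroid. Bright-on-dark polarity is
# assumed; pass `invert = TRUE` for the opposite contrast.

# Gaussian blur with the kernel capped to the frame size (EBImage refuses
# filters larger than the image).
gblur_capped <- function(frame, sigma) {
  r_max <- min(dim(frame)) - 2L
  if (r_max %% 2L == 0L) r_max <- r_max - 1L
  r <- min(2L * as.integer(ceiling(3 * sigma)) + 1L, r_max)
  EBImage::gblur(frame, sigma = sigma, radius = r, boundary = "replicate")
}

# Difference-of-Gaussians band-pass tuned to a disk of the given radius.
bandpass <- function(frame, radius_px) {
  s1 <- max(1, radius_px / 2)
  s2 <- max(2, radius_px * 1.5)
  gblur_capped(frame, s1) - gblur_capped(frame, s2)
}

# Strict 8-neighbour local maxima of a matrix, excluding a 1-px border.
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ri <- 2:(H - 1); ci <- 2:(W - 1)
  ctr <- m[ri, ci]
  ok <- ctr > m[ri - 1, ci] & ctr > m[ri + 1, ci] &
    ctr > m[ri, ci - 1] & ctr > m[ri, ci + 1] &
    ctr > m[ri - 1, ci - 1] & ctr > m[ri - 1, ci + 1] &
    ctr > m[ri + 1, ci - 1] & ctr > m[ri + 1, ci + 1]
  w <- which(ok, arr.ind = TRUE)
  cbind(row = w[, 1] + 1L, col = w[, 2] + 1L)
}

# Intensity-weighted centroid refinement in a window of half-width `hw`,
# re-centred until stable. Background is the window's lower intensity
# quartile, subtracted and clamped so dark pixels carry no weight. The
# refined centre may drift at most `hw` from the starting point, so a seed
# on featureless background cannot wander off to a distant blob.
refine_centroid <- function(frame, x, y, hw, max_iter = 5) {
  H <- nrow(frame); W <- ncol(frame)
  x0 <- x; y0 <- y
  for (it in seq_len(max_iter)) {
    r0 <- round(y) + 1L
    c0 <- round(x) + 1L
    rows <- max(1L, r0 - hw):min(H, r0 + hw)
    cols <- max(1L, c0 - hw):min(W, c0 + hw)
    win <- frame[rows, cols, drop = FALSE]
    w <- pmax(win - quantile(win, 0.25), 0)
    sw <- sum(w)
    if (sw <= 0) return(c(x = x, y = y, ok = 0))
    yc <- sum(rowSums(w) * (rows - 1L)) / sw
    xc <- sum(colSums(w) * (cols - 1L)) / sw
    xc <- max(min(xc, x0 + hw), x0 - hw)
    yc <- max(min(yc, y0 + hw), y0 - hw)
    moved <- max(abs(xc - x), abs(yc - y))
    x <- xc; y <- yc
    if (moved < 0.05) break
  }
  c(x = x, y = y, ok = 1)
}

#' Detect pillar tops in a reference frame
#'
#' @param reference_frame A single grayscale frame (numeric matrix) or an
#'   [image_stack()], in which case [choose_reference_frame()] picks the
#'   frame.
#' @param expected_radius_px Approximate pillar-top radius in pixels
#'   (>= 1).
#' @param min_separation_px Minimum centre-to-centre distance retained by
#'   non-maximum suppression; default 1.5 x the radius.
#' @param threshold Relative band-pass response floor (fraction of the
#'   maximum response) below which maxima are discarded.
#' @param invert Set `TRUE` for dark pillars on a bright background.
#' @return A `pillar_set`: a data.frame `pillar_id, x_px, y_px, radius_px,
#'   score`, sorted row-major, with the reference frame index (if known) as
#'   an attribute. Zero detections yield an empty set with a warning.
#' @export
detect_pillars <- function(reference_frame, expected_radius_px,
                           min_separation_px = 1.5 * expected_radius_px,
                           threshold = 0.3, invert = FALSE) {
  ref_idx <- NA_integer_
  if (inherits(reference_frame, "image_stack")) {
    ref_idx <- choose_reference_frame(reference_frame)
    reference_frame <- reference_frame$frames[[ref_idx]]
  }
  if (!is.matrix(reference_frame)) {
    pb_stop("reference_frame must be a single 2-D frame",
            "pillarbeat_invalid_parameter")
  }
  if (expected_radius_px < 1) {
    pb_stop("expected_radius_px must be >= 1",
            "pillarbeat_invalid_parameter")
  }
  rng <- range(reference_frame)
  if (!all(is.finite(rng)) || diff(rng) < 1e-9) {
    pb_stop("degenerate reference frame (constant or saturated)",
            "pillarbeat_degenerate_input")
  }
  if (invert) reference_frame <- max(reference_frame) - reference_frame

  bp <- bandpass(reference_frame, expected_radius_px)
  cand <- local_maxima(bp)
  scores <- bp[cand]
  keep <- scores > threshold * max(bp)
  cand <- cand[keep, , drop = FALSE]
  scores <- scores[keep]

  # greedy non-maximum suppression, strongest first
  o <- order(scores, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  scores <- scores[o]
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { sel[1] <- TRUE; next }
    prev <- cand[sel, , drop = FALSE]
    d2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
    sel[i] <- all(d2 >= min_separation_px^2)
  }
  cand <- cand[sel, , drop = FALSE]
  scores <- scores[sel]

  if (nrow(cand) == 0L) {
    pb_warn("no pillars detected", "pillarbeat_empty_detection")
    out <- data.frame(pillar_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), radius_px = numeric(0),
                      score = numeric(0))
    return(structure(out, class = c("pillar_set", "data.frame"),
                     reference_frame = ref_idx))
  }

  hw <- ceiling(expected_radius_px)
  # centroid on a lightly smoothed frame: averages pixel noise without
  # biasing a symmetric blob
  sm <- gblur_capped(reference_frame, max(1, expected_radius_px / 4))
  ctr <- t(apply(cand, 1, function(rc) {
    refine_centroid(sm, x = rc[2] - 1, y = rc[1] - 1, hw = hw)
  }))
  o <- order_row_major(ctr[, "x"], ctr[, "y"],
                       row_tol = min_separation_px / 2)
  out <- data.frame(
    pillar_id = seq_along(o),
    x_px = ctr[o, "x"], y_px = ctr[o, "y"],
    radius_px = expected_radius_px,
    score = scores[o] / max(scores)
  )
  structure(out, class = c("pillar_set", "data.frame"),
            reference_frame = ref_idx)
}

#' Refine user-supplied pillar seeds
#'
#' Each seed point is refined to the sub-pixel intensity centroid in a local
#' window; input ordering is preserved. Seeds landing on featureless
#' background are retained but flagged with a low score and a warning.
#'
#' @param points A two-column matrix or data.frame of `(x_px, y_px)` seeds.
#' @param reference_frame A grayscale frame matrix.
#' @param expected_radius_px Refinement window half-width in pixels.
#' @return A `pillar_set` data.frame as in [detect_pillars()], with a
#'   `low_score` logical column.
#' @export
accept_manual_seeds <- function(points, reference_frame,
                                expected_radius_px = 8) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) {
    out <- data.frame(pillar_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), radius_px = numeric(0),
                      score = numeric(0), low_score = logical(0))
    return(structure(out, class = c("pillar_set", "data.frame")))
  }
  H <- nrow(reference_frame); W <- ncol(reference_frame)
  bad <- points[, 1] < 0 | points[, 1] > W - 1 |
    points[, 2] < 0 | points[, 2] > H - 1
  if (any(bad)) {
    i <- which(bad)[1]
    pb_stop(sprintf("seed %d at (%.1f, %.1f) is outside the %d x %d image",
                    i, points[i, 1], points[i, 2], W, H),
            "pillarbeat_index_error")
  }
  bp <- bandpass(reference_frame, expected_radius_px)
  hw <- ceiling(expected_radius_px)
  ctr <- t(apply(points, 1, function(p) {
    refine_centroid(reference_frame, x = p[1], y = p[2], hw = hw)
  }))
  sc <- bp[cbind(pmin(pmax(round(ctr[, "y"]) + 1, 1), H),
                 pmin(pmax(round(ctr[, "x"]) + 1, 1), W))]
  rel <- sc / max(bp)
  low <- rel < 0.3
  if (any(low)) {
    pb_warn(sprintf("%d seed(s) have low blob score; retained but flagged",
                    sum(low)), "pillarbeat_low_score_seed")
  }
  out <- data.frame(pillar_id = seq_len(nrow(points)),
                    x_px = ctr[, "x"], y_px = ctr[, "y"],
                    radius_px = expected_radius_px,
                    score = rel, low_score = low)
  structure(out, class = c("pillar_set", "data.frame"))
}

#' Pick a reference ("most relaxed") frame
#'
#' Default policy: the frame minimising the mean absolute intensity
#' difference from the temporal median image — a proxy for the resting
#' configuration, since contraction excursions are brief. A second pass
#' recomputes the median over the quietest quarter of frames, so that
#' frames straddling a slow relaxation tail do not pull the reference off
#' rest. The median image is computed over at most `max_median_frames`
#' evenly spaced frames.
#'
#' @param stack An [image_stack()].
#' @param max_median_frames Subsample size for the median image.
#' @return The 1-based frame index.
#' @export
choose_reference_frame <- function(stack, max_median_frames = 40) {
  n <- length(stack$frames)
  if (n == 1L) return(1L)
  median_image <- function(which_frames) {
    idx <- unique(round(seq(1, length(which_frames),
                            length.out = min(length(which_frames),
                                             max_median_frames))))
    arr <- simplify2array(stack$frames[which_frames[idx]])
    apply(arr, c(1, 2), median)
  }
  score_against <- function(med) {
    vapply(stack$frames, function(f) mean(abs(f - med)), numeric(1))
  }
  score <- score_against(median_image(seq_len(n)))
  quiet <- order(score)[seq_len(max(2L, n %/% 4L))]
  score <- score_against(median_image(sort(quiet)))
  which.min(score)
}

#' Fit a square lattice to detected centres
#'
#' Estimates the lattice orientation from nearest-neighbour bond angles
#' (fourfold circular mean), assigns integer lattice indices, and refines
#' origin and pitch by least squares. Used as a geometric QC check against
#' the nominal array pitch.
#'
#' @param centers A `pillar_set` or any data.frame with `x_px, y_px`
#'   (>= 4 centres, not collinear).
#' @return A list: `pitch_px`, `orientation_deg` (in `[0, 90)`),
#'   `median_nn_px` (median nearest-neighbour spacing), `residuals_px`
#'   (per-centre distance to the fitted lattice point).
#' @export
fit_lattice <- function(centers) {
  x <- centers$x_px; y <- centers$y_px
  n <- length(x)
  if (n < 4L) {
    pb_stop("lattice fit needs at least 4 centres",
            "pillarbeat_insufficient_data")
  }
  xy <- cbind(x, y)
  sv <- svd(scale(xy, scale = FALSE))$d
  if (sv[2] < 1e-6 * sv[1]) {
    pb_stop("centres are collinear; square-lattice fit is degenerate",
            "pillarbeat_insufficient_data")
  }
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  nn_d <- D[cbind(seq_len(n), nn)]
  pitch0 <- median(nn_d)
  # fourfold (square-symmetry) mean of bond angles, physical y-up frame
  th <- atan2(-(y[nn] - y), x[nn] - x)
  ang <- atan2(mean(sin(4 * th)), mean(cos(4 * th))) / 4
  # rotate into lattice frame and assign integer indices
  ca <- cos(ang); sa <- sin(ang)
  xr <- x * ca - (-y) * sa # work in y-up coordinates
  yr <- x * sa + (-y) * ca
  i <- round((xr - min(xr)) / pitch0)
  j <- round((yr - min(yr)) / pitch0)
  # least squares: xr = x0 + p*i, yr = y0 + p*j with common pitch p
  fit <- stats::lm.fit(
    x = rbind(cbind(1, 0, i), cbind(0, 1, j)),
    y = c(xr, yr))
  p <- fit$coefficients[3]
  res <- matrix(fit$residuals, ncol = 2)
  residuals_px <- sqrt(res[, 1]^2 + res[, 2]^2)
  list(pitch_px = unname(p),
       orientation_deg = (ang * 180 / pi) %% 90,
       median_nn_px = pitch0,
       residuals_px = residuals_px)
}
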