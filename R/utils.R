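# Internal helpers: classed conditions, angle conventions, RNG hygiene.

pb_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "pillarbeat_error")))
}

pb_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "pillarbeat_warning")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    pb_stop(sprintf("`%s` must be a single positive finite number", name),
            "pillarbeat_invalid_parameter")
  }
  invisible(x)
}

#' @noRd
#' Convert an image-frame displacement (x right, y down) to a physical angle
#' in degrees, counterclockwise from +x with y up, mapped to [0, 360).
angle_from_image_vec <- function(dx, dy) {
  ang <- atan2(-dy, dx) * 180 / pi
  (ang %% 360)
}

#' @noRd
#' Unit displacement in image coordinates for a physical angle in degrees.
image_vec_from_angle <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(x = cos(th), y = -sin(th))
}

# Run `expr` with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic fan-out of a top-level seed into per-stage seeds (< 2^31).
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Row-major ordering of (x, y) points grouped into rows by y-gaps.
order_row_major <- function(x, y, row_tol) {
  if (length(x) == 0L) return(integer(0))
  o <- order(y, x)
  ys <- y[o]
  row_id <- cumsum(c(1, diff(ys) > row_tol))
  o[order(row_id, x[o])]
}
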