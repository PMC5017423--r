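# End-to-end pipeline: detect -> track -> displace/force -> beats ->
# summary, with every artifact written as CSV/JSON next to a run manifest.

#' Run the full analysis pipeline on a stack
#'
#' Executes pillar detection, sub-pixel tracking, deflection and force
#' conversion, beat segmentation, and the alignment summary, writing
#' `pillars.csv`, `tracks.csv`, `beats.csv`, `summary.json`, the effective
#' `config.json` and a `manifest.json` (package version, seed, config
#' hash, stage log) to `out_dir`. Reruns with identical inputs and seed
#' reproduce the outputs byte for byte.
#'
#' @param input An [image_stack()], a path to a multi-page TIFF, or a
#'   simulation list from [render_stack()].
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Integer seed recorded in the manifest and fanned out to any
#'   stage that draws random numbers (none of the core stages do).
#' @param stop_after Last stage to execute: `"detect"`, `"track"`, or
#'   `"beat"` (default, the full analysis).
#' @return A list: `pillars`, `trajectories`, `series` (with force),
#'   `beats`, `summary`, `manifest`.
#' @export
run_pipeline <- function(input, config = analysis_config(), out_dir = NULL,
                         seed = 1L, stop_after = c("beat", "track",
                                                   "detect")) {
  stop_after <- match.arg(stop_after)
  stages <- character(0)
  run_stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      pb_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "pillarbeat_stage_error", stage = name)
    })
  }

  stack <- run_stage("load", {
    if (inherits(input, "image_stack")) input
    else if (is.list(input) && inherits(input$stack, "image_stack"))
      input$stack
    else read_stack(input, config$image.pixel_size_um,
                    config$image.frame_rate_fps)
  })

  pillars <- run_stage("detect", {
    detect_pillars(stack,
                   expected_radius_px = config$detect.expected_radius_px,
                   min_separation_px = config$detect.min_separation_px,
                   threshold = config$detect.threshold,
                   invert = config$detect.invert)
  })

  trajectories <- series <- beats <- summary <- NULL
  if (stop_after != "detect") {
    trajectories <- run_stage("track", {
      track_pillars(stack, pillars,
                    window_px = config$track.window_px,
                    quality_threshold = config$track.quality_threshold)
    })
    series <- run_stage("displace", {
      s <- trajectories_to_displacement(
        trajectories, method = config$track.reference_method)
      to_force(s, config_spring_constant(config))
    })
  }
  if (stop_after == "beat") {
    beats <- run_stage("beat", {
      segment_beats(series,
                    min_amplitude_um = config$beat.min_amplitude_um,
                    min_separation_s = config$beat.min_separation_s,
                    k = config_spring_constant(config))
    })
    summary <- run_stage("summarize", {
      dur <- length(stack$frames) / stack$frame_rate_fps
      per <- lapply(split(beats, beats$pillar_id), function(b) {
        f <- beat_frequency(b, dur)
        list(pillar_id = b$pillar_id[1], n_beats = nrow(b),
             mean_amp_um = mean(b$amp_um),
             peak_force_un = max(b$peak_force_un),
             freq_hz = f$freq_hz)
      })
      align <- if (nrow(beats)) {
        alignment_summary(beats$angle_deg, n_bins = config$beat.n_bins)
      } else NULL
      list(duration_s = dur, n_pillars = nrow(pillars),
           n_beats = nrow(beats),
           mean_amplitude_um = if (nrow(beats)) mean(beats$amp_um) else NA,
           mean_peak_force_un = if (nrow(beats)) mean(beats$peak_force_un)
                                else NA,
           per_pillar = unname(per),
           alignment = if (is.null(align)) NULL else unclass(align))
    })
  }

  manifest <- list(
    package = "pillarbeat",
    version = as.character(utils::packageVersion("pillarbeat")),
    seed = seed,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) derive_seed(seed, s)), stages),
    config_hash = config_hash(config),
    stages = stages,
    n_frames = length(stack$frames),
    n_pillars = nrow(pillars),
    stop_after = stop_after
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(d, f) write.csv(d, file.path(out_dir, f),
                                     row.names = FALSE)
    wcsv(as.data.frame(pillars), "pillars.csv")
    if (!is.null(series)) {
      tracks <- series[, c("pillar_id", "frame", "time_s", "x_px", "y_px",
                           "dx_um", "dy_um", "d_um", "force_un",
                           "quality", "lost")]
      wcsv(tracks, "tracks.csv")
    }
    if (!is.null(beats)) {
      wcsv(beats[, c("pillar_id", "beat_index", "t_start_s", "t_peak_s",
                     "t_end_s", "amp_um", "peak_force_un", "angle_deg")],
           "beats.csv")
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(pillars = pillars, trajectories = trajectories, series = series,
       beats = beats, summary = summary, manifest = manifest)
}

#' Plot a displacement (or force) series
#'
#' Deflection magnitude against time, one panel per pillar id present.
#'
#' @param x A `displacement_series` data.frame.
#' @param pillar_ids Which pillars to draw (default: first).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.displacement_series <- function(x, pillar_ids = NULL, ...) {
  if (is.null(pillar_ids)) pillar_ids <- x$pillar_id[1]
  sd <- x[x$pillar_id %in% pillar_ids, ]
  plot(sd$time_s, sd$d_um, type = "l", xlab = "time (s)",
       ylab = "deflection (um)", ...)
  invisible(x)
}
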