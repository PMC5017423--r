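# Analysis configuration: flat dotted keys with defaults mirroring a
# 16 um x 48 um PDMS pillar array (E = 0.5 MPa, 23 um pitch, 25 fps).

config_defaults <- function() {
  list(
    pillar.diameter_um = 16,
    pillar.length_um = 48,
    pillar.spring_constant_n_per_m = NA_real_, # optional calibrated override
    material.youngs_modulus_mpa = 0.5,
    lattice.pitch_um = 23,
    image.pixel_size_um = 0.5,
    image.frame_rate_fps = 25,
    detect.expected_radius_px = 16,
    detect.min_separation_px = 24,
    detect.threshold = 0.3,
    detect.invert = FALSE,
    track.window_px = 5,
    track.quality_threshold = 0.5,
    track.reference_method = "percentile",
    beat.min_amplitude_um = 0.5,
    beat.min_separation_s = 0.3,
    beat.n_bins = 36
  )
}

#' Analysis configuration
#'
#' Flat dotted keys with validated defaults. Unknown keys are rejected.
#' If `pillar.spring_constant_n_per_m` is set (e.g. from an AFM
#' calibration) it takes precedence over the beam-formula value computed
#' from the geometry and modulus.
#'
#' @param ... Named overrides of the default keys.
#' @param provenance Free-text note on where the values came from
#'   (file path, CLI overrides); recorded alongside outputs.
#' @return An `analysis_config` list.
#' @examples
#' cfg <- analysis_config(material.youngs_modulus_mpa = 1)
#' @export
analysis_config <- function(..., provenance = "defaults") {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      pb_stop(sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")),
              "pillarbeat_config_error")
    }
    cfg[names(over)] <- over
  }
  num_keys <- setdiff(names(cfg),
                      c("detect.invert", "track.reference_method",
                        "pillar.spring_constant_n_per_m"))
  for (kk in num_keys) {
    if (!is.numeric(cfg[[kk]]) || length(cfg[[kk]]) != 1L ||
        !is.finite(cfg[[kk]]) || cfg[[kk]] <= 0) {
      pb_stop(sprintf("config key `%s` must be a positive number", kk),
              "pillarbeat_config_error")
    }
  }
  structure(c(cfg, list(provenance = provenance)),
            class = "analysis_config")
}

#' Read a flat key/value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' coerced to numeric or logical where possible. Unknown keys are
#' rejected.
#'
#' @param path Path to the config file.
#' @param ... Further overrides applied on top of the file (CLI wins over
#'   file, file wins over defaults).
#' @return An `analysis_config`.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) {
    pb_stop(sprintf("no such config file: %s", path),
            "pillarbeat_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    pb_stop(sprintf("malformed config line: '%s'", lines[which(bad)[1]]),
            "pillarbeat_config_error")
  }
  vals <- lapply(kv, function(p) {
    v <- p[2]
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 1)
  over <- list(...)
  vals[names(over)] <- over
  do.call(analysis_config,
          c(vals, list(provenance = sprintf("file:%s", path))))
}

#' Spring constant implied by a configuration
#'
#' Uses the calibrated `pillar.spring_constant_n_per_m` override when set;
#' otherwise evaluates the beam formula from the configured geometry and
#' modulus.
#'
#' @param cfg An [analysis_config()].
#' @return A [spring_constant()].
#' @export
config_spring_constant <- function(cfg) {
  ko <- cfg$pillar.spring_constant_n_per_m
  if (!is.null(ko) && !is.na(ko)) return(new_spring_constant(ko))
  spring_constant(
    pillar_geometry(cfg$pillar.diameter_um, cfg$pillar.length_um),
    elastic_material(cfg$material.youngs_modulus_mpa))
}

# Stable hash of the effective configuration (md5 of its canonical JSON).
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
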