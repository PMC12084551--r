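#' Analysis configuration
#'
#' Central bag of tunable parameters with validated defaults. Unknown
#' names are rejected.
#'
#' @param pixel_size_A Pixel size fallback, Angstrom/pixel (default 0.83).
#' @param mt_outer_diameter_nm Filament outer diameter used to convert
#'   center distances to wall-to-wall gaps (default 25).
#' @param coherence_threshold Polarity confidence threshold on the mean
#'   resultant length (default 0.8).
#' @param max_edge_gap_nm Pair-gating maximum edge gap (default 50).
#' @param min_overlap_frac Pair-gating minimum mutual overlap (default 0.5).
#' @param pause_band_nm_s Dynamics pause velocity band, nm/s (default 0.3).
#' @param min_phase_s Minimum phase duration, s (default 5).
#' @param velocity_window Sliding-window width in samples for the local
#'   velocity estimate (default 5).
#' @param min_sin_tilt Near-end-on exclusion threshold (default 0.1).
#' @param tie_tol_deg Ambiguity band around 90 degrees when classifying
#'   pairs (default 1).
#' @param seed Optional integer seed recorded in run manifests.
#' @param out_dir Optional output directory for CLI runs.
#' @return A validated named list of class `mt_config`.
#' @export
mt_config <- function(pixel_size_A = 0.83, mt_outer_diameter_nm = 25,
                      coherence_threshold = 0.8, max_edge_gap_nm = 50,
                      min_overlap_frac = 0.5, pause_band_nm_s = 0.3,
                      min_phase_s = 5, velocity_window = 5,
                      min_sin_tilt = 0.1, tie_tol_deg = 1,
                      seed = NULL, out_dir = NULL) {
  cfg <- list(pixel_size_A = pixel_size_A,
              mt_outer_diameter_nm = mt_outer_diameter_nm,
              coherence_threshold = coherence_threshold,
              max_edge_gap_nm = max_edge_gap_nm,
              min_overlap_frac = min_overlap_frac,
              pause_band_nm_s = pause_band_nm_s,
              min_phase_s = min_phase_s,
              velocity_window = velocity_window,
              min_sin_tilt = min_sin_tilt,
              tie_tol_deg = tie_tol_deg,
              seed = seed, out_dir = out_dir)
  for (nm in setdiff(names(cfg), c("seed", "out_dir"))) {
    stopifnot_scalar_pos(cfg[[nm]], nm)
  }
  if (cfg$coherence_threshold > 1) abort("coherence_threshold must be <= 1")
  if (cfg$min_overlap_frac > 1) abort("min_overlap_frac must be <= 1")
  structure(cfg, class = "mt_config")
}

#' Load configuration overrides from a JSON file
#'
#' Reads a flat JSON object and merges it over [mt_config()] defaults.
#' Unknown keys are an error.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @param ... Further overrides taking precedence over the file.
#' @return `mt_config` list.
#' @export
mt_config_from_json <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(mt_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(mt_config, vals)
}
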