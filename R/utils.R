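# internal helpers shared across modules

#' @importFrom rlang abort warn inform
NULL

# Reduce an angle in degrees to [-180, 180)
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. One explicit RNG per generator call.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Single documented image <-> math frame conversion. Image pixels have the
# origin top-left with y increasing downward; internal geometry uses a
# right-handed frame (y up) in nanometres. This is the only place the y
# axis is flipped.
px_to_nm <- function(x_px, y_px, pixel_size_A) {
  list(x_nm = x_px * pixel_size_A / 10, y_nm = -y_px * pixel_size_A / 10)
}

nm_to_px <- function(x_nm, y_nm, pixel_size_A) {
  list(x_px = x_nm * 10 / pixel_size_A, y_px = -y_nm * 10 / pixel_size_A)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}
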