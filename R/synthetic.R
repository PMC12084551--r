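#' Synthetic bundled-filament STAR dataset with known ground truth
#'
#' Generates `n_pairs` bundles, each of two straight filaments on its own
#' synthetic micrograph: a random in-plane orientation, a wall-to-wall
#' gap drawn uniformly from `gap_range_nm`, and per-particle Euler angles
#' psi = filament polarity + Gaussian noise, tilt = 90 + Gaussian noise
#' clipped to \[0, 180\], rot uniform. The class composition is exact:
#' `round(n_pairs * fraction_parallel)` pairs are parallel and the rest
#' antiparallel, in a seed-determined random order, so the ground truth
#' composition is reproducible rather than binomially scattered.
#'
#' @param n_pairs Number of filament pairs.
#' @param fraction_parallel Fraction of pairs whose second filament shares
#'   the first's polarity (in \[0, 1\]).
#' @param gap_range_nm Length-2 positive range for the uniform edge gap.
#' @param angle_noise_deg SD of the per-particle psi noise (degrees).
#' @param coord_noise_nm SD of the per-particle coordinate jitter (nm).
#' @param particles_per_filament Segments per filament (default 12).
#' @param filament_length_nm Filament length (default 440 nm).
#' @param tilt_noise_deg SD of the tilt noise around 90 degrees
#'   (default 5).
#' @param pixel_size_A Pixel size written into the table (default 0.83).
#' @param outer_diameter_nm Outer diameter used to convert gaps to center
#'   distances (default 25 nm).
#' @param seed Integer seed; same seed, same dataset.
#' @return List with `particles` (a particle tibble as from
#'   [read_particles()]) and `truth` (generator parameters plus
#'   per-filament polarities and per-pair classes and gaps).
#' @export
gen_bundle_star <- function(n_pairs = 177, fraction_parallel = 91 / 177,
                            gap_range_nm = c(2, 14), angle_noise_deg = 5,
                            coord_noise_nm = 1, particles_per_filament = 12,
                            filament_length_nm = 440, tilt_noise_deg = 5,
                            pixel_size_A = 0.83, outer_diameter_nm = 25,
                            seed = 42) {
  stopifnot_scalar_pos(n_pairs, "n_pairs")
  if (fraction_parallel < 0 || fraction_parallel > 1) {
    abort("fraction_parallel must lie in [0, 1]")
  }
  if (length(gap_range_nm) != 2L || any(gap_range_nm <= 0) ||
      gap_range_nm[2] < gap_range_nm[1]) {
    abort("gap_range_nm must be a positive increasing range")
  }
  if (angle_noise_deg < 0 || coord_noise_nm < 0 || tilt_noise_deg < 0) {
    abort("noise parameters must be non-negative")
  }
  stopifnot_scalar_pos(particles_per_filament, "particles_per_filament")
  if (particles_per_filament < 2) abort("particles_per_filament must be >= 2")

  with_seed(seed, {
    n_par <- round(n_pairs * fraction_parallel)
    classes <- sample(c(rep("parallel", n_par),
                        rep("antiparallel", n_pairs - n_par)))
    m <- particles_per_filament
    offs <- seq(-filament_length_nm / 2, filament_length_nm / 2,
                length.out = m)
    parts <- vector("list", n_pairs)
    fil_truth <- vector("list", n_pairs)
    pair_truth <- vector("list", n_pairs)
    for (k in seq_len(n_pairs)) {
      mic <- sprintf("synthetic_%04d.mrc", k)
      alpha <- stats::runif(1, -180, 180)
      dirv <- c(cos(deg2rad(alpha)), sin(deg2rad(alpha)))
      perp <- c(-dirv[2], dirv[1])
      ctr <- c(stats::runif(1, 400, 1600), stats::runif(1, -1600, -400))
      gap <- stats::runif(1, gap_range_nm[1], gap_range_nm[2])
      cdist <- gap + outer_diameter_nm
      pol2 <- if (classes[k] == "parallel") alpha else wrap_angle(alpha + 180)
      one_filament <- function(tube, center, pol) {
        x <- center[1] + offs * dirv[1] + stats::rnorm(m, 0, coord_noise_nm)
        y <- center[2] + offs * dirv[2] + stats::rnorm(m, 0, coord_noise_nm)
        px <- nm_to_px(x, y, pixel_size_A)
        tibble::tibble(
          micrograph_id = mic,
          x_px = px$x_px, y_px = px$y_px,
          rot_deg = stats::runif(m, -180, 180),
          tilt_deg = pmin(pmax(90 + stats::rnorm(m, 0, tilt_noise_deg), 0), 180),
          psi_deg = wrap_angle(pol + stats::rnorm(m, 0, angle_noise_deg)),
          tube_id = tube,
          pixel_size_A = pixel_size_A)
      }
      parts[[k]] <- dplyr::bind_rows(
        one_filament(1L, ctr, alpha),
        one_filament(2L, ctr + cdist * perp, pol2))
      fil_truth[[k]] <- tibble::tibble(
        micrograph_id = mic, tube_id = c(1L, 2L), pair_id = k,
        polarity_angle_deg = c(alpha, pol2))
      pair_truth[[k]] <- tibble::tibble(
        pair_id = k, micrograph_id = mic,
        orientation_class = classes[k], edge_gap_nm = gap)
    }
    particles <- dplyr::bind_rows(parts)
    class(particles) <- c("mt_particles", class(particles))
    list(
      particles = particles,
      truth = list(
        params = list(n_pairs = n_pairs, fraction_parallel = fraction_parallel,
                      gap_range_nm = gap_range_nm,
                      angle_noise_deg = angle_noise_deg,
                      coord_noise_nm = coord_noise_nm,
                      particles_per_filament = particles_per_filament,
                      filament_length_nm = filament_length_nm,
                      tilt_noise_deg = tilt_noise_deg,
                      pixel_size_A = pixel_size_A,
                      outer_diameter_nm = outer_diameter_nm, seed = seed),
        n_parallel = n_par,
        filaments = dplyr::bind_rows(fil_truth),
        pairs = dplyr::bind_rows(pair_truth)))
  })
}

#' Synthetic co-sedimentation densitometry with known Kd
#'
#' Pellet fractions follow the single-site hyperbola with multiplicative
#' Gaussian noise (clipped to \[0, 1\]); lane intensities are lognormal so
#' pellet and supernatant report realistic arbitrary units.
#'
#' @param kd_uM,bmax True dissociation constant (> 0) and plateau.
#' @param concentrations_uM Ligand concentrations (default 8 points
#'   log-spaced 0.1 to 20).
#' @param cv_noise Multiplicative noise CV (default 0.05, >= 0).
#' @param n_replicates Replicates per concentration (default 3).
#' @param condition Condition label (default "synthetic").
#' @param mean_intensity,intensity_sdlog Lognormal lane-intensity model.
#' @param seed Integer seed.
#' @return List with `data` (condition, concentration_uM, replicate,
#'   pellet, supernatant) and `truth`.
#' @export
gen_cosed <- function(kd_uM, bmax = 1,
                      concentrations_uM = 10^seq(log10(0.1), log10(20),
                                                 length.out = 8),
                      cv_noise = 0.05, n_replicates = 3,
                      condition = "synthetic",
                      mean_intensity = 1000, intensity_sdlog = 0.2,
                      seed = 1) {
  stopifnot_scalar_pos(kd_uM, "kd_uM")
  stopifnot_scalar_pos(bmax, "bmax")
  if (cv_noise < 0) abort("cv_noise must be >= 0")
  stopifnot_scalar_pos(n_replicates, "n_replicates")
  if (any(concentrations_uM <= 0)) abort("concentrations must be positive")

  with_seed(seed, {
    grid <- tidyr::expand_grid(concentration_uM = sort(concentrations_uM),
                               replicate = seq_len(n_replicates))
    f0 <- bmax * grid$concentration_uM / (kd_uM + grid$concentration_uM)
    f <- pmin(pmax(f0 * (1 + stats::rnorm(nrow(grid), 0, cv_noise)), 0), 1)
    i0 <- stats::rlnorm(nrow(grid), log(mean_intensity), intensity_sdlog)
    data <- tibble::tibble(
      condition = condition,
      concentration_uM = grid$concentration_uM,
      replicate = grid$replicate,
      pellet = f * i0,
      supernatant = (1 - f) * i0)
    list(data = data,
         truth = list(kd_uM = kd_uM, bmax = bmax, cv_noise = cv_noise,
                      n_replicates = n_replicates,
                      concentrations_uM = sort(concentrations_uM),
                      condition = condition, seed = seed))
  })
}

#' Simulated dynamic-instability traces with known rates
#'
#' Continuous-time Markov chain over growth, pause and shrinkage states:
#' growth goes to shrinkage at `f_cat` and to pause at
#' `pause_entry_rate`; pause returns to growth at `pause_exit_rate` and
#' collapses at `f_cat`; shrinkage is rescued to growth at `f_res`.
#' Length integrates the state velocity (pause velocity 0) and is
#' reflected at zero (immediate regrowth from the seed). Traces are
#' sampled on a uniform grid with additive Gaussian measurement noise.
#'
#' @param v_g Growth velocity, nm/s (> 0).
#' @param v_s Shrinkage velocity, nm/s (< 0).
#' @param f_cat,f_res Catastrophe and rescue rates, 1/s (>= 0).
#' @param pause_entry_rate,pause_exit_rate Pause entry/exit rates, 1/s.
#' @param duration_s,dt_s Trace length and sampling interval (s).
#' @param n_traces Number of traces (default 50).
#' @param length_noise_nm Additive measurement noise SD (default 20 nm).
#' @param initial_length_nm Starting length (default 0).
#' @param condition Condition label.
#' @param seed Integer seed.
#' @return List with `data` (trace_id, condition, time_s, length_nm),
#'   and `truth` including per-trace true state occupancy times.
#' @export
gen_traces <- function(v_g, v_s, f_cat, f_res,
                       pause_entry_rate = 0, pause_exit_rate = 0,
                       duration_s = 600, dt_s = 1, n_traces = 50,
                       length_noise_nm = 20, initial_length_nm = 0,
                       condition = "synthetic", seed = 1) {
  if (v_g <= 0) abort("v_g must be > 0")
  if (v_s >= 0) abort("v_s must be < 0")
  rates <- c(f_cat, f_res, pause_entry_rate, pause_exit_rate)
  if (any(rates < 0)) abort("rates must be >= 0")
  if (dt_s >= duration_s) abort("dt_s must be smaller than duration_s")

  vel <- c(growth = v_g, pause = 0, shrinkage = v_s)
  out_rates <- list(
    growth = c(shrinkage = f_cat, pause = pause_entry_rate),
    pause = c(growth = pause_exit_rate, shrinkage = f_cat),
    shrinkage = c(growth = f_res))

  with_seed(seed, {
    grid <- seq(0, duration_s, by = dt_s)
    traces <- vector("list", n_traces)
    occ <- matrix(0, n_traces, 3,
                  dimnames = list(NULL, c("growth", "pause", "shrinkage")))
    for (k in seq_len(n_traces)) {
      tau <- 0; state <- "growth"; len <- initial_length_nm
      bt <- tau; bl <- len; bs <- state  # breakpoint records
      while (tau < duration_s) {
        rr <- out_rates[[state]]
        tot <- sum(rr)
        dt_ev <- if (tot > 0) stats::rexp(1, tot) else Inf
        # a shrinking filament may hit zero first: reflect into growth
        t_zero <- if (state == "shrinkage") len / abs(vel[["shrinkage"]]) else Inf
        step <- min(dt_ev, t_zero, duration_s - tau)
        occ[k, state] <- occ[k, state] + step
        len <- len + vel[[state]] * step
        tau <- tau + step
        if (tau >= duration_s) { bt <- c(bt, tau); bl <- c(bl, len); break }
        if (t_zero < dt_ev) {
          len <- 0; state <- "growth"
        } else {
          state <- names(rr)[sample.int(length(rr), 1, prob = rr)]
        }
        bt <- c(bt, tau); bl <- c(bl, len); bs <- c(bs, state)
      }
      true_len <- stats::approx(bt, bl, xout = grid, rule = 2)$y
      traces[[k]] <- tibble::tibble(
        trace_id = k, condition = condition, time_s = grid,
        length_nm = pmax(true_len + stats::rnorm(length(grid), 0,
                                                 length_noise_nm), 0))
    }
    list(
      data = dplyr::bind_rows(traces),
      truth = list(v_g = v_g, v_s = v_s, f_cat = f_cat, f_res = f_res,
                   pause_entry_rate = pause_entry_rate,
                   pause_exit_rate = pause_exit_rate,
                   duration_s = duration_s, dt_s = dt_s,
                   n_traces = n_traces, length_noise_nm = length_noise_nm,
                   initial_length_nm = initial_length_nm,
                   condition = condition, seed = seed,
                   state_time = tibble::as_tibble(occ) |>
                     dplyr::mutate(trace_id = seq_len(n_traces),
                                   .before = 1)))
  })
}

#' Serialize / restore generator ground truth
#'
#' Ground truth is written as JSON with tibbles as row-wise records, so a
#' dataset and its truth can be archived next to each other and the
#' record round-trips exactly at JSON precision.
#'
#' @param truth Ground-truth list from a generator.
#' @param path Output JSON path.
#' @return `path` invisibly (write) or the restored list (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(names(x), c("filaments", "pairs", "state_time"))) {
    x[[nm]] <- tibble::as_tibble(as.data.frame(x[[nm]]))
  }
  x
}
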