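#' Fraction of material in the pellet lane
#'
#' Densitometric pellet fraction pellet / (pellet + supernatant), with
#' optional background subtraction from matched control lanes (intensities
#' are floored at zero after subtraction). Vectorized.
#'
#' @param pellet,supernatant Band intensities (arbitrary units, >= 0).
#' @param pellet_background,supernatant_background Control-lane intensities
#'   subtracted before forming the ratio (default 0).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
band_fraction <- function(pellet, supernatant,
                          pellet_background = 0, supernatant_background = 0) {
  if (any(pellet < 0 | supernatant < 0)) {
    abort("intensities must be non-negative")
  }
  p <- pmax(pellet - pellet_background, 0)
  s <- pmax(supernatant - supernatant_background, 0)
  tot <- p + s
  if (any(tot <= 0)) {
    abort("pellet and supernatant are both zero: fraction undefined",
          class = "mtkit_zero_lane")
  }
  p / tot
}

# single-site hyperbola; the quadratic variant accounts for probe depletion
isotherm_fraction <- function(conc, kd, bmax, model = "hyperbolic",
                              probe_uM = NULL) {
  if (model == "hyperbolic") {
    bmax * conc / (kd + conc)
  } else {
    P <- probe_uM
    b <- kd + conc + P
    bmax * (b - sqrt(pmax(b^2 - 4 * conc * P, 0))) / (2 * P)
  }
}

#' Fit a single-site binding isotherm
#'
#' Fits f(\[L\]) = Bmax \[L\] / (Kd + \[L\]) to pellet fractions by
#' nonlinear least squares (Levenberg-Marquardt), one fit per replicate
#' plus one pooled fit over all points. Kd is initialized at the
#' concentration nearest half the maximal fraction and Bmax at the maximal
#' fraction; Bmax is bounded in (0, 1.05\] or can be fixed. A quadratic
#' tight-binding variant accounting for probe depletion is available via
#' `model = "quadratic"` (requires `probe_uM`).
#'
#' @param data Tibble with concentration, fraction-bound and replicate
#'   columns.
#' @param conc,fraction,replicate Column names (defaults
#'   `concentration_uM`, `fraction_bound`, `replicate`).
#' @param model `"hyperbolic"` (default) or `"quadratic"`.
#' @param probe_uM Total probe concentration for the quadratic model.
#' @param fix_bmax Optional fixed Bmax; when `NULL` (default) Bmax is
#'   fitted.
#' @return Object of class `isotherm_fit`: per-replicate estimates,
#'   `kd_mean`/`kd_sd` across replicates, the pooled fit, and the data.
#'   Has [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
fit_isotherm <- function(data, conc = "concentration_uM",
                         fraction = "fraction_bound", replicate = "replicate",
                         model = c("hyperbolic", "quadratic"),
                         probe_uM = NULL, fix_bmax = NULL) {
  model <- match.arg(model)
  if (model == "quadratic") stopifnot_scalar_pos(probe_uM, "probe_uM")
  L <- data[[conc]]
  f <- data[[fraction]]
  rep_id <- if (replicate %in% names(data)) data[[replicate]]
            else rep(1L, nrow(data))
  if (length(unique(L)) < 3L) {
    abort("need at least 3 distinct concentrations to fit an isotherm")
  }
  span <- max(L) / max(min(L[L > 0]), .Machine$double.eps)
  if (span < 10) {
    warn("concentration span is under one order of magnitude; the fit may be poorly constrained")
  }
  if (diff(range(f)) <= 1e-6 * max(abs(f), 1)) {
    warn("fractions show no concentration dependence: Kd is unconstrained")
  }

  fit_one <- function(Li, fi) {
    fmax <- max(fi)
    kd0 <- Li[which.min(abs(fi - fmax / 2))]
    kd0 <- max(kd0, min(Li[Li > 0]) / 10)
    P <- if (is.null(probe_uM)) 0 else probe_uM
    pred <- function(L, kd, bmax) {
      isotherm_fraction(L, kd, bmax, model = model,
                        probe_uM = if (model == "quadratic") P else NULL)
    }
    df <- data.frame(L = Li, f = fi)
    res <- tryCatch({
      if (is.null(fix_bmax)) {
        ft <- minpack.lm::nlsLM(
          f ~ pred(L, kd, bmax),
          data = df, start = list(kd = kd0, bmax = max(fmax, 0.05)),
          lower = c(kd = 1e-9, bmax = 1e-6),
          upper = c(kd = Inf, bmax = 1.05),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(ft)
        list(kd = unname(cf["kd"]), bmax = unname(cf["bmax"]),
             resid_rms = sqrt(mean(stats::resid(ft)^2)), converged = TRUE)
      } else {
        ft <- minpack.lm::nlsLM(
          f ~ pred(L, kd, fix_bmax),
          data = df, start = list(kd = kd0), lower = c(kd = 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        list(kd = unname(stats::coef(ft)["kd"]), bmax = fix_bmax,
             resid_rms = sqrt(mean(stats::resid(ft)^2)), converged = TRUE)
      }
    }, error = function(e) {
      abort(sprintf("isotherm fit failed to converge: %s",
                    conditionMessage(e)), class = "mtkit_fit_failure")
    })
    if (res$kd > 5 * max(Li)) {
      warn(sprintf(
        "fitted Kd (%.3g uM) exceeds 5x the maximum concentration: poorly constrained",
        res$kd))
    }
    res
  }

  per_rep <- dplyr::bind_rows(lapply(split(seq_along(L), rep_id), function(ix) {
    r <- fit_one(L[ix], f[ix])
    tibble::tibble(replicate = rep_id[ix][1], kd_uM = r$kd, bmax = r$bmax,
                   resid_rms = r$resid_rms, converged = r$converged)
  }))
  pooled <- fit_one(L, f)

  structure(list(
    per_replicate = per_rep,
    kd_mean = mean(per_rep$kd_uM),
    kd_sd = if (nrow(per_rep) >= 2) stats::sd(per_rep$kd_uM) else NA_real_,
    bmax_mean = mean(per_rep$bmax),
    bmax_sd = if (nrow(per_rep) >= 2) stats::sd(per_rep$bmax) else NA_real_,
    pooled = pooled, model = model, probe_uM = probe_uM,
    data = tibble::tibble(concentration_uM = L, fraction_bound = f,
                          replicate = rep_id)
  ), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("Single-site isotherm fit (%s model)\n", x$model))
  cat(sprintf("  Kd = %.3g +/- %.3g uM (mean +/- SD over %d replicates)\n",
              x$kd_mean, x$kd_sd, nrow(x$per_replicate)))
  cat(sprintf("  Bmax = %.3g +/- %.3g\n", x$bmax_mean, x$bmax_sd))
  cat(sprintf("  pooled: Kd = %.3g uM, Bmax = %.3g, rms residual %.3g\n",
              x$pooled$kd, x$pooled$bmax, x$pooled$resid_rms))
  invisible(x)
}

#' @export
tidy.isotherm_fit <- function(x, ...) x$per_replicate

#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble::tibble(kd_mean_uM = x$kd_mean, kd_sd_uM = x$kd_sd,
                 bmax_mean = x$bmax_mean, bmax_sd = x$bmax_sd,
                 kd_pooled_uM = x$pooled$kd, bmax_pooled = x$pooled$bmax,
                 resid_rms = x$pooled$resid_rms,
                 n_replicates = nrow(x$per_replicate), model = x$model)
}

#' Per-concentration dose-response summary
#'
#' Mean and SD of the pellet fraction per condition and concentration; no
#' curve is fitted. Accepts either a precomputed `fraction` column or raw
#' `pellet`/`supernatant` intensities (converted via [band_fraction()]).
#'
#' @param data Tibble with `condition`, `concentration_uM`, `replicate`
#'   and either `fraction` or `pellet` + `supernatant` columns.
#' @return Tibble: condition, concentration, `n`, `mean_fraction`,
#'   `sd_fraction` (NA with `sd_defined = FALSE` for single replicates).
#' @export
dose_response_summary <- function(data) {
  if (!"condition" %in% names(data)) {
    abort("`data` must have a `condition` column")
  }
  if (!"fraction" %in% names(data)) {
    if (!all(c("pellet", "supernatant") %in% names(data))) {
      abort("`data` needs either a `fraction` or `pellet`+`supernatant` columns")
    }
    data$fraction <- band_fraction(data$pellet, data$supernatant)
  }
  data |>
    dplyr::group_by(.data$condition, .data$concentration_uM) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fraction = mean(.data$fraction),
      sd_fraction = if (dplyr::n() >= 2) stats::sd(.data$fraction) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(sd_defined = .data$n >= 2) |>
    dplyr::arrange(.data$condition, .data$concentration_uM)
}

#' Apparent molecular weight and oligomeric state from SEC
#'
#' Fits the standard log-linear column calibration log10(MW) against
#' elution volume, inverts it at the sample's elution volume, and rounds
#' the ratio of apparent to theoretical monomer weight to the nearest
#' oligomeric state (floored at 1).
#'
#' @param standards Tibble with `mw_kDa` and `elution_mL` columns
#'   (>= 3 standards; elution must increase strictly as MW decreases).
#' @param sample_elution_mL Elution volume of the sample.
#' @param theoretical_mw_kDa Theoretical monomer molecular weight.
#' @return Object of class `sec_result` with a [generics::tidy()] method:
#'   calibration slope/intercept, `apparent_mw_kDa`, `ratio`,
#'   `oligomer_state`, `extrapolated` flag.
#' @export
sec_oligomer <- function(standards, sample_elution_mL, theoretical_mw_kDa) {
  if (nrow(standards) < 3L) abort("need at least 3 calibration standards")
  stopifnot_scalar_pos(theoretical_mw_kDa, "theoretical_mw_kDa")
  st <- standards[order(standards$elution_mL), , drop = FALSE]
  if (any(diff(st$elution_mL) <= 0) || any(diff(st$mw_kDa) >= 0)) {
    abort("calibration must be strictly monotonic: MW decreasing with elution volume")
  }
  fit <- stats::lm(log10(mw_kDa) ~ elution_mL, data = st)
  cf <- stats::coef(fit)
  extrap <- sample_elution_mL < min(st$elution_mL) ||
    sample_elution_mL > max(st$elution_mL)
  if (extrap) {
    warn("sample elutes outside the calibration range: extrapolating")
  }
  apparent <- 10^(cf[[1]] + cf[[2]] * sample_elution_mL)
  ratio <- apparent / theoretical_mw_kDa
  structure(list(
    slope = cf[[2]], intercept = cf[[1]],
    apparent_mw_kDa = apparent,
    theoretical_mw_kDa = theoretical_mw_kDa,
    ratio = ratio,
    oligomer_state = max(1L, as.integer(round(ratio))),
    extrapolated = extrap,
    standards = tibble::as_tibble(st)
  ), class = "sec_result")
}

#' @export
print.sec_result <- function(x, ...) {
  cat(sprintf(
    "SEC: apparent MW %.1f kDa / theoretical %.1f kDa = %.2f -> %d-mer%s\n",
    x$apparent_mw_kDa, x$theoretical_mw_kDa, x$ratio, x$oligomer_state,
    if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' @export
tidy.sec_result <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 apparent_mw_kDa = x$apparent_mw_kDa,
                 theoretical_mw_kDa = x$theoretical_mw_kDa,
                 ratio = x$ratio, oligomer_state = x$oligomer_state,
                 extrapolated = x$extrapolated)
}
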