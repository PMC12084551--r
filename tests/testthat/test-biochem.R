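test_that("band_fraction computes the pellet fraction", {
  expect_equal(band_fraction(60, 40), 0.6)
  expect_equal(band_fraction(0, 100), 0)
  expect_error(band_fraction(0, 0), class = "mtkit_zero_lane")
  expect_error(band_fraction(-1, 2), "non-negative")
})

test_that("band_fraction is scale invariant and supports backgrounds", {
  p <- runif(20, 1, 100); s <- runif(20, 1, 100)
  expect_equal(band_fraction(7 * p, 7 * s), band_fraction(p, s),
               tolerance = 1e-12)
  f <- band_fraction(p, s)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(band_fraction(110, 60, pellet_background = 10,
                             supernatant_background = 20), 100 / 140)
})

test_that("fit_isotherm is exact on noiseless data", {
  conc <- 10^seq(log10(0.1), log10(20), length.out = 8)
  for (kd in c(0.1, 0.69, 5)) {
    d <- tibble::tibble(concentration_uM = rep(conc, 3),
                        fraction_bound = rep(0.9 * conc / (kd + conc), 3),
                        replicate = rep(1:3, each = 8))
    fit <- fit_isotherm(d)
    expect_equal(fit$pooled$kd, kd, tolerance = 1e-6)
    expect_equal(fit$pooled$bmax, 0.9, tolerance = 1e-6)
    expect_equal(fit$kd_mean, kd, tolerance = 1e-6)
    expect_equal(fit$kd_sd, 0, tolerance = 1e-6)
  }
})

test_that("quadratic depletion model recovers its own truth", {
  conc <- 10^seq(log10(0.1), log10(20), length.out = 8)
  kd <- 0.5; P <- 0.2; bmax <- 1
  b <- kd + conc + P
  f <- bmax * (b - sqrt(b^2 - 4 * conc * P)) / (2 * P)
  d <- tibble::tibble(concentration_uM = conc, fraction_bound = f,
                      replicate = 1L)
  fit <- fit_isotherm(d, model = "quadratic", probe_uM = P)
  expect_equal(fit$pooled$kd, kd, tolerance = 1e-5)
})

test_that("flat data warns about an unconstrained Kd", {
  d <- tibble::tibble(concentration_uM = c(0.1, 1, 10),
                      fraction_bound = c(0.8, 0.8, 0.8), replicate = 1L)
  expect_warning(fit_isotherm(d), "no concentration dependence")
})

test_that("too few concentrations is a precondition error", {
  d <- tibble::tibble(concentration_uM = c(1, 1, 10, 10),
                      fraction_bound = c(0.3, 0.31, 0.7, 0.72),
                      replicate = 1L)
  expect_error(fit_isotherm(d), "at least 3 distinct concentrations")
})

test_that("narrow concentration span warns", {
  d <- tibble::tibble(concentration_uM = c(1, 2, 4),
                      fraction_bound = c(0.4, 0.55, 0.7), replicate = 1L)
  expect_warning(fit_isotherm(d), "order of magnitude")
})

test_that("tidy/glance expose per-replicate and pooled estimates", {
  sim <- gen_cosed(kd_uM = 1, seed = 4)
  d <- sim$data
  d$fraction_bound <- band_fraction(d$pellet, d$supernatant)
  fit <- fit_isotherm(d)
  td <- tidy(fit)
  expect_equal(nrow(td), 3L)
  expect_true(all(c("replicate", "kd_uM", "bmax") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_replicates, 3L)
  expect_true(gl$kd_pooled_uM > 0)
})

test_that("dose_response_summary mirrors triplicate arithmetic", {
  d <- tibble::tibble(condition = "FL", concentration_uM = 16,
                      replicate = 1:3, fraction = c(0.58, 0.60, 0.62))
  s <- dose_response_summary(d)
  expect_equal(s$mean_fraction, 0.60, tolerance = 1e-12)
  expect_equal(s$sd_fraction, 0.02, tolerance = 1e-12)
  expect_true(s$sd_defined)
})

test_that("single replicate flags an undefined SD", {
  d <- tibble::tibble(condition = "FL", concentration_uM = 4,
                      replicate = 1, fraction = 0.4)
  s <- dose_response_summary(d)
  expect_true(is.na(s$sd_fraction))
  expect_false(s$sd_defined)
})

test_that("two constructs keep their ordering in the summary", {
  d <- tibble::tibble(
    condition = rep(c("FL", "dC"), each = 3),
    concentration_uM = 16, replicate = rep(1:3, 2),
    fraction = c(0.59, 0.60, 0.61, 0.22, 0.23, 0.24))
  s <- dose_response_summary(d)
  fl <- s$mean_fraction[s$condition == "FL"]
  dc <- s$mean_fraction[s$condition == "dC"]
  expect_equal(fl, 0.60, tolerance = 1e-12)
  expect_equal(dc, 0.23, tolerance = 1e-12)
  expect_gt(fl, dc)
})

test_that("dose_response_summary accepts raw pellet/supernatant", {
  d <- tibble::tibble(condition = "FL", concentration_uM = 16,
                      replicate = 1:2, pellet = c(60, 58),
                      supernatant = c(40, 42))
  s <- dose_response_summary(d)
  expect_equal(s$mean_fraction, 0.59, tolerance = 1e-12)
  expect_error(dose_response_summary(
    tibble::tibble(concentration_uM = 1, fraction = 0.5)), "condition")
})

test_that("sec_oligomer is exact on a log-linear calibration", {
  # construct an exactly log-linear column: log10(MW) = 4 - 0.2 V
  vols <- c(10, 11.5, 13)
  stds <- tibble::tibble(mw_kDa = 10^(4 - 0.2 * vols), elution_mL = vols)
  r <- sec_oligomer(stds, sample_elution_mL = 12, theoretical_mw_kDa = 10^(4 - 0.2 * 12) / 2)
  expect_equal(r$apparent_mw_kDa, 10^(4 - 0.2 * 12), tolerance = 1e-9)
  expect_equal(r$ratio, 2, tolerance = 1e-9)
  expect_equal(r$oligomer_state, 2L)
})

test_that("sec_oligomer calls the dimer on a realistic standard set", {
  stds <- tibble::tibble(mw_kDa = c(66, 29, 12.4),
                         elution_mL = c(10.0, 12.0, 13.9))
  r <- sec_oligomer(stds, sample_elution_mL = 10.0, theoretical_mw_kDa = 34)
  expect_equal(r$apparent_mw_kDa, 66, tolerance = 66 * 0.05)
  expect_equal(r$oligomer_state, 2L)
  # near-monomeric ratio rounds to state 1
  mono <- sec_oligomer(stds, sample_elution_mL = 12.0,
                       theoretical_mw_kDa = 30)
  expect_equal(mono$oligomer_state, 1L)
})

test_that("sec_oligomer validates standards and warns on extrapolation", {
  expect_error(sec_oligomer(tibble::tibble(mw_kDa = c(66, 29),
                                           elution_mL = c(10, 12)), 11, 34),
               "at least 3")
  bad <- tibble::tibble(mw_kDa = c(66, 29, 40), elution_mL = c(10, 12, 13.9))
  expect_error(sec_oligomer(bad, 11, 34), "monotonic")
  good <- tibble::tibble(mw_kDa = c(66, 29, 12.4),
                         elution_mL = c(10, 12, 13.9))
  expect_warning(sec_oligomer(good, 15, 34), "extrapolating")
})
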