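test_that("fit_axis recovers an exact line", {
  x <- seq(0, 10, length.out = 20)
  ax <- fit_axis(cbind(x, 2 * x + 1))
  expect_equal(abs(sum(ax$direction * c(1, 2) / sqrt(5))), 1, tolerance = 1e-9)
  expect_equal(ax$residual_rms, 0, tolerance = 1e-9)
  two <- fit_axis(rbind(c(0, 0), c(3, 4)))
  expect_equal(two$arclength, 5, tolerance = 1e-12)
  expect_equal(two$residual_rms, 0, tolerance = 1e-12)
})

test_that("fit_axis residual tracks the generating noise", {
  set.seed(3)
  x <- seq(0, 100, length.out = 50)
  y <- 0.5 * x + rnorm(50, 0, 1)
  ax <- fit_axis(cbind(x, y))
  expect_lt(abs(ax$residual_rms - 1), 0.3)
})

test_that("coincident points are rejected", {
  expect_error(fit_axis(rbind(c(1, 1), c(1, 1), c(1, 1))), "coincident")
  expect_error(fit_axis(rbind(c(1, 1))), "at least 2")
})

test_that("gap_distance reproduces the worked arithmetic", {
  mk <- function(y0) fit_axis(cbind(seq(0, 400, length.out = 10), y0))
  g <- gap_distance(mk(0), mk(28.785))
  expect_equal(g$edge_gap_nm, 3.785, tolerance = 1e-9)
  expect_equal(g$center_distance_nm, 28.785, tolerance = 1e-9)
  expect_false(g$overlapping)
  # identical axes: center 0, edge -25, flagged overlapping
  same <- gap_distance(mk(0), mk(0))
  expect_equal(same$center_distance_nm, 0, tolerance = 1e-12)
  expect_equal(same$edge_gap_nm, -25, tolerance = 1e-12)
  expect_true(same$overlapping)
})

test_that("gap_distance is symmetric and errors without overlap", {
  a <- fit_axis(cbind(seq(0, 100, length.out = 8), 0))
  b <- fit_axis(cbind(seq(20, 120, length.out = 8), 30 + 0.01 *
                        seq(20, 120, length.out = 8)))
  g1 <- gap_distance(a, b)
  g2 <- gap_distance(b, a)
  expect_equal(g1$center_distance_nm, g2$center_distance_nm, tolerance = 1e-6)
  far <- fit_axis(cbind(seq(500, 600, length.out = 8), 0))
  expect_error(gap_distance(a, far), class = "mtkit_no_overlap")
})

test_that("slightly converging lines average to the midpoint separation", {
  # numeric-integration oracle at fine sampling
  x <- seq(0, 100, length.out = 40)
  a <- fit_axis(cbind(x, 0))
  b <- fit_axis(cbind(x, 30 + 0.02 * x))
  g <- gap_distance(a, b, n_samples = 5000)
  oracle <- mean(abs(30 + 0.02 * seq(0, 100, length.out = 1e5)) /
                   sqrt(1 + 0.02^2))
  expect_equal(g$center_distance_nm, oracle, tolerance = 1e-3)
})

test_that("classify_pair thresholds at 90 degrees with an ambiguity band", {
  p <- classify_pair(0, atan2(0.2, 0.98) * 180 / pi)
  expect_equal(p$orientation_class, "parallel")
  expect_equal(p$angle_between_deg, 11.53, tolerance = 0.01)
  expect_equal(classify_pair(0, 180)$orientation_class, "antiparallel")
  expect_equal(classify_pair(0, 180)$angle_between_deg, 180)
  expect_equal(classify_pair(0, 90)$orientation_class, "ambiguous")
  # symmetry
  expect_equal(classify_pair(17, 141)$angle_between_deg,
               classify_pair(141, 17)$angle_between_deg)
})

test_that("find_pairs gates on edge gap and overlap", {
  x <- seq(0, 400, length.out = 10)
  mk_tab <- function(tube, y0) tibble::tibble(
    micrograph_id = "m.mrc", tube_id = tube,
    x_px = x, y_px = -y0 * 10 / 0.83,  # image-pixel input, y flipped
    rot_deg = 0, tilt_deg = 90, psi_deg = 0, pixel_size_A = 0.83)
  close_tab <- dplyr::bind_rows(mk_tab(1L, 0), mk_tab(2L, 30))
  fl <- close_tab |> group_filaments() |> fit_axes()
  pr <- find_pairs(fl)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$edge_gap_nm, 5, tolerance = 0.2)
  far_tab <- dplyr::bind_rows(mk_tab(1L, 0), mk_tab(2L, 200))
  expect_equal(nrow(far_pairs <- far_tab |> group_filaments() |> fit_axes() |>
                      find_pairs()), 0L)
  # three mutually close axes give exactly C(3,2) = 3 pairs
  tri <- dplyr::bind_rows(mk_tab(1L, 0), mk_tab(2L, 30), mk_tab(3L, 60))
  expect_equal(nrow(tri |> group_filaments() |> fit_axes() |> find_pairs()), 3L)
})

test_that("non-confident polarity excludes a pair with a reason", {
  sim <- gen_bundle_star(n_pairs = 3, seed = 2)
  res <- trace_bundles(sim$particles)
  fl <- res$filaments
  fl$confident[1] <- FALSE
  pairs <- classify_pairs(find_pairs(fl), fl)
  bad <- pairs$micrograph_id == fl$micrograph_id[1]
  expect_true(all(is.na(pairs$orientation_class[bad])))
  expect_equal(unique(pairs$excluded_reason[bad]), "low-coherence polarity")
})

test_that("bundle_summary reproduces the composition arithmetic", {
  pairs <- tibble::tibble(
    orientation_class = c(rep("parallel", 91), rep("antiparallel", 86)),
    edge_gap_nm = seq(3.785, 14, length.out = 177))
  s <- bundle_summary(pairs)
  expect_equal(s$n_total, 177L)
  expect_equal(s$fraction_parallel, 91 / 177, tolerance = 1e-12)
  expect_equal(s$gap_min_nm, 3.785)
  expect_equal(sum(s$histogram$count), 177L)
  td <- tidy(s)
  expect_equal(td$n_parallel, 91L)
})

test_that("one-sided composition matches the exact binomial", {
  pairs <- tibble::tibble(orientation_class = rep("parallel", 10),
                          edge_gap_nm = rep(5, 10))
  s <- bundle_summary(pairs)
  expect_equal(s$binomial_p, 2 * 0.5^10, tolerance = 1e-12)
})

test_that("empty pair set errors", {
  expect_error(bundle_summary(tibble::tibble(orientation_class = character(0),
                                             edge_gap_nm = numeric(0))),
               "no classified pairs")
})

test_that("dimer_rise_delta reports 0.01-A delta and 1-decimal display", {
  d <- dimer_rise_delta(83.96, 82.25)
  expect_equal(d$delta_A, 1.71)
  expect_equal(d$delta_display, "1.7")
  expect_equal(dimer_rise_delta(80, 80)$delta_A, 0)
  expect_equal(dimer_rise_delta(80, 83)$delta_A, -3)
  expect_error(dimer_rise_delta(-1, 80), "positive")
})

test_that("zero-noise synthetic bundles are recovered exactly", {
  sim <- gen_bundle_star(n_pairs = 12, angle_noise_deg = 0,
                         coord_noise_nm = 0, tilt_noise_deg = 0, seed = 8)
  res <- trace_bundles(sim$particles)
  got <- res$pairs[order(res$pairs$micrograph_id), ]
  truth <- sim$truth$pairs[order(sim$truth$pairs$micrograph_id), ]
  expect_equal(nrow(got), 12L)
  expect_identical(got$orientation_class, truth$orientation_class)
  expect_equal(got$edge_gap_nm, truth$edge_gap_nm, tolerance = 1e-6)
})

test_that("noisy synthetic bundles: classes exact, gaps within 2x coord noise", {
  sim <- gen_bundle_star(n_pairs = 30, angle_noise_deg = 10,
                         coord_noise_nm = 1, seed = 13)
  res <- trace_bundles(sim$particles)
  got <- res$pairs[order(res$pairs$micrograph_id), ]
  truth <- sim$truth$pairs[order(sim$truth$pairs$micrograph_id), ]
  expect_identical(got$orientation_class, truth$orientation_class)
  expect_lt(sqrt(mean((got$edge_gap_nm - truth$edge_gap_nm)^2)), 2)
})

test_that("global 180-degree polarity flip leaves the summary unchanged", {
  sim <- gen_bundle_star(n_pairs = 20, seed = 6)
  res1 <- trace_bundles(sim$particles)
  flipped <- sim$particles
  flipped$psi_deg <- ((flipped$psi_deg + 180 + 180) %% 360) - 180
  res2 <- trace_bundles(flipped)
  expect_equal(tidy(res2$summary), tidy(res1$summary), tolerance = 1e-9)
})
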