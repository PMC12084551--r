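ramp_trace <- function() {
  tibble::tibble(time_s = 0:120, length_nm = 14.73 * (0:120))
}

test_that("a pure ramp is a single growth phase at the exact slope", {
  ph <- segment_trace(ramp_trace())
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$kind, "growth")
  expect_equal(ph$velocity_nm_s, 14.73, tolerance = 1e-9)
  expect_equal(ph$duration_s, 120)
})

test_that("ramp up then steep ramp down is growth, shrinkage, 1 catastrophe", {
  tr <- tibble::tibble(
    time_s = 0:79,
    length_nm = c(10 * (0:59), 10 * 59 - 40 * (1:20)),
    trace_id = 1L, condition = "c")
  ph <- segment_trace(tr)
  expect_equal(ph$kind, c("growth", "shrinkage"))
  expect_equal(ph$velocity_nm_s, c(10, -40), tolerance = 1e-9)
  st <- event_statistics(segment_traces(tr))
  expect_equal(st$n_cat, 1L)
  expect_equal(st$n_res, 0L)
})

test_that("a flat trace is a single pause", {
  ph <- segment_trace(tibble::tibble(time_s = 0:99, length_nm = rep(50, 100)))
  expect_equal(ph$kind, "pause")
  expect_equal(nrow(ph), 1L)
})

test_that("a too-short trace errors", {
  expect_error(segment_trace(tibble::tibble(time_s = 0:2,
                                            length_nm = c(0, 1, 2))),
               "shorter than one velocity window")
  expect_error(segment_trace(tibble::tibble(time_s = c(0, 1, 1, 2, 3, 4),
                                            length_nm = rep(0, 6))),
               "strictly increasing")
})

test_that("phases tile the trace exactly", {
  sim <- gen_traces(v_g = 10, v_s = -200, f_cat = 0.01, f_res = 0.05,
                    duration_s = 300, n_traces = 5, length_noise_nm = 15,
                    seed = 2)
  ph <- segment_traces(sim$data)
  for (id in unique(ph$trace_id)) {
    p <- ph[ph$trace_id == id, ]
    expect_equal(sum(p$duration_s), 300)
    expect_equal(p$t_start[-1], utils::head(p$t_end, -1))
    expect_equal(p$t_start[1], 0)
  }
})

test_that("noise permutation does not change phase counts for well-separated velocities", {
  set.seed(14)
  clean <- c(10 * (0:99), 10 * 99 - 300 * (1:5), rep(10 * 99 - 1500, 45))
  clean <- pmax(clean, 0)
  noise <- rnorm(length(clean), 0, 15)
  n1 <- nrow(segment_trace(tibble::tibble(
    time_s = seq_along(clean) - 1, length_nm = clean + noise)))
  n2 <- nrow(segment_trace(tibble::tibble(
    time_s = seq_along(clean) - 1, length_nm = clean + sample(noise))))
  expect_equal(n1, n2)
})

test_that("event_statistics computes frequencies from hand-built phases", {
  ph <- tibble::tibble(
    trace_id = 1L, condition = "c",
    phase = 1:5,
    kind = c("growth", "shrinkage", "pause", "shrinkage", "growth"),
    t_start = c(0, 40, 50, 90, 100),
    t_end = c(40, 50, 90, 100, 120),
    duration_s = c(40, 10, 40, 10, 20),
    velocity_nm_s = c(10, -100, 0, -100, 10),
    n_points = c(40, 10, 40, 10, 20))
  st <- event_statistics(ph)
  expect_equal(st$n_cat, 2L)       # growth->shrink and pause->shrink
  expect_equal(st$n_res, 2L)       # shrink->pause and shrink->growth
  expect_equal(st$f_cat, 2 / 100)  # growth+pause time = 100 s
  expect_equal(st$f_res, 2 / 20)
  expect_equal(st$growth_rate_mean, 10)
  expect_equal(st$pause_mean_s, 40)
  st_g <- event_statistics(ph, cat_denominator = "growth")
  expect_equal(st_g$f_cat, 2 / 60)
})

test_that("no shrinkage time flags f_res undefined rather than zero", {
  ph <- tibble::tibble(trace_id = 1L, condition = "c", phase = 1L,
                       kind = "growth", t_start = 0, t_end = 100,
                       duration_s = 100, velocity_nm_s = 5, n_points = 100)
  st <- event_statistics(ph)
  expect_true(is.na(st$f_res))
  expect_false(st$f_res_defined)
  expect_error(event_statistics(ph[0, ]), "no phases")
})

test_that("adding a catastrophe increases f_cat at fixed duration", {
  base <- tibble::tibble(
    trace_id = 1L, condition = "c", phase = 1:2,
    kind = c("growth", "shrinkage"),
    t_start = c(0, 90), t_end = c(90, 100), duration_s = c(90, 10),
    velocity_nm_s = c(10, -100), n_points = c(90, 10))
  more <- tibble::tibble(
    trace_id = 1L, condition = "c", phase = 1:4,
    kind = c("growth", "shrinkage", "growth", "shrinkage"),
    t_start = c(0, 45, 50, 95), t_end = c(45, 50, 95, 100),
    duration_s = c(45, 5, 45, 5),
    velocity_nm_s = c(10, -100, 10, -100), n_points = c(45, 5, 45, 5))
  expect_gt(event_statistics(more)$f_cat, event_statistics(base)$f_cat)
})

test_that("growth rate is recovered from noisy control-like traces", {
  sim <- gen_traces(v_g = 14.73, v_s = -300, f_cat = 0.005, f_res = 0.02,
                    duration_s = 600, dt_s = 1, n_traces = 20,
                    length_noise_nm = 20, seed = 11)
  st <- event_statistics(segment_traces(sim$data))
  expect_lt(abs(st$growth_rate_mean - 14.73) / 14.73, 0.05)
  expect_lt(abs(st$f_cat - 0.005) / 0.005, 0.30)
})

test_that("slow growth with pauses is recovered within tolerance", {
  sim <- gen_traces(v_g = 1.71, v_s = -300, f_cat = 0.001, f_res = 0.02,
                    pause_entry_rate = 0.01, pause_exit_rate = 0.005,
                    duration_s = 600, dt_s = 1, n_traces = 20,
                    length_noise_nm = 20, seed = 12)
  st <- event_statistics(segment_traces(sim$data))
  expect_lt(abs(st$growth_rate_mean - 1.71) / 1.71, 0.12)
  expect_gt(st$n_pauses, 0)
})

test_that("refine = FALSE reproduces the plain windowed segmentation on clean data", {
  ph <- segment_trace(ramp_trace(), refine = FALSE)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$velocity_nm_s, 14.73, tolerance = 1e-9)
})
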