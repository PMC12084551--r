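#' Segment a length-vs-time trace into growth, pause and shrinkage phases
#'
#' Piecewise-linear segmentation of a filament length trace. A sliding
#' least-squares window estimates the local velocity at every sample;
#' samples are labelled growth, pause or shrinkage against a symmetric
#' velocity band; runs of equal labels become phases; phases shorter than
#' `min_phase_s` are absorbed into their longer neighbor. Phase
#' boundaries are then refined by an exact two-line least-squares
#' breakpoint search between adjacent phases, each phase's velocity is
#' re-estimated as the least-squares slope over its span, and phase kinds
#' are reassigned from those fitted slopes (merging neighbors that end up
#' in the same kind). The refinement makes boundary placement robust to
#' measurement noise much larger than the per-window velocity resolution
#' while leaving clean traces untouched.
#'
#' @param trace Tibble with `time_s` (strictly increasing, roughly
#'   uniform) and `length_nm` columns.
#' @param pause_band_nm_s Half-width of the pause velocity band
#'   (default 0.3 nm/s).
#' @param min_phase_s Minimum phase duration; shorter phases are absorbed
#'   (default 5 s).
#' @param window Sliding-window width in samples for the initial velocity
#'   estimate (default 5).
#' @param refine Run the breakpoint refinement pass (default TRUE).
#' @return Tibble of phases: `phase`, `kind`, `t_start`, `t_end`,
#'   `duration_s`, `velocity_nm_s`, `n_points`. Phases tile the trace.
#' @export
segment_trace <- function(trace, pause_band_nm_s = 0.3, min_phase_s = 5,
                          window = 5, refine = TRUE) {
  t <- trace$time_s
  y <- trace$length_nm
  n <- length(t)
  if (n < window) abort("trace shorter than one velocity window")
  if (any(diff(t) <= 0)) abort("time_s must be strictly increasing")

  v <- window_slopes(t, y, window)
  kind <- ifelse(v > pause_band_nm_s, "growth",
                 ifelse(v < -pause_band_nm_s, "shrinkage", "pause"))

  r <- rle(kind)
  si <- cumsum(c(1L, utils::head(r$lengths, -1)))
  kinds <- r$values

  sigma <- if (refine) estimate_noise_sd(y) else 0

  reclassify <- function(si) {
    repeat {
      vel <- phase_slopes(si, t, y, n)
      new_kinds <- ifelse(vel > pause_band_nm_s, "growth",
                          ifelse(vel < -pause_band_nm_s, "shrinkage", "pause"))
      mg <- merge_same_kind_checked(si, new_kinds, t, y, sigma)
      if (length(mg$si) == length(si)) return(mg)
      si <- mg$si
    }
  }

  if (refine && length(si) > 1L) {
    # sharpen the window-smeared boundaries, drop boundaries whose
    # flanking slopes are statistically indistinguishable (noise
    # flickers), absorb short phases, sharpen again and reclassify from
    # the fitted slopes; a final absorption pass removes leftovers
    si <- refine_boundaries(si, t, y)
    si <- prune_boundaries(si, t, y, sigma)
    si <- split_phases(si, t, y, sigma)
    si <- prune_boundaries(si, t, y, sigma)
    ph <- absorb_short_phases(si, reclassify(si)$kinds, t, min_phase_s,
                              y = y, sigma = sigma)
    si <- ph$si
    for (pass in 1:2) si <- refine_boundaries(si, t, y)
    rc <- reclassify(si)
    ph <- absorb_short_phases(rc$si, rc$kinds, t, min_phase_s,
                              y = y, sigma = sigma)
    si <- drop_flicker_phases(ph$si, t, y, sigma)
    si <- split_phases(si, t, y, sigma)
    for (pass in 1:2) si <- refine_boundaries(si, t, y)
    rc <- reclassify(si)
    ph <- absorb_short_phases(rc$si, rc$kinds, t, min_phase_s,
                              y = y, sigma = sigma)
    rc <- reclassify(ph$si)
    si <- rc$si; kinds <- rc$kinds
  } else {
    ph <- absorb_short_phases(si, kinds, t, min_phase_s)
    rc <- reclassify(ph$si)
    si <- rc$si; kinds <- rc$kinds
  }
  vel <- phase_slopes(si, t, y, n)
  ends <- c(si[-1], n + 1L)
  t_start <- t[si]
  t_end <- ifelse(ends > n, t[n], t[ends])
  tibble::tibble(
    phase = seq_along(si), kind = kinds,
    t_start = t_start, t_end = t_end,
    duration_s = t_end - t_start,
    velocity_nm_s = vel,
    n_points = as.integer(ends - si))
}

# centered sliding-window least-squares slopes, edges clamped
window_slopes <- function(t, y, w) {
  n <- length(t)
  w <- min(w, n)
  m <- n - w + 1L
  cs <- function(z) c(0, cumsum(z))
  St <- cs(t); Sy <- cs(y); Stt <- cs(t * t); Sty <- cs(t * y)
  k <- seq_len(m)
  sx <- St[k + w] - St[k]; sy <- Sy[k + w] - Sy[k]
  sxx <- Stt[k + w] - Stt[k]; sxy <- Sty[k + w] - Sty[k]
  slope <- (w * sxy - sx * sy) / (w * sxx - sx^2)
  h <- (w - 1L) %/% 2L
  idx <- pmin(pmax(seq_len(n) - h, 1L), m)
  slope[idx]
}

# least-squares slope of samples si[i] .. si[i+1]-1 (last phase to n)
phase_slopes <- function(si, t, y, n) {
  ends <- c(si[-1] - 1L, n)
  vapply(seq_along(si), function(i) {
    ix <- si[i]:ends[i]
    if (length(ix) < 2L) return(0)
    tt <- t[ix] - mean(t[ix])
    sum(tt * y[ix]) / sum(tt * tt)
  }, numeric(1))
}

merge_same_kind <- function(si, kinds) {
  keep <- c(TRUE, kinds[-1] != utils::head(kinds, -1))
  list(si = si[keep], kinds = kinds[keep])
}

# merge same-kind neighbors only when the boundary carries no structure:
# two pauses separated by an unresolved level step must stay apart, or
# the merged span refits to a shallow bogus slope. A boundary is kept
# when dropping it raises the RSS by at least the split penalty. With
# sigma = 0 (noise-free traces) this reduces to plain merge_same_kind.
merge_same_kind_checked <- function(si, kinds, t, y, sigma, z = 3) {
  if (sigma <= 0) return(merge_same_kind(si, kinds))
  n <- length(t)
  rss <- make_rss(t, y)
  repeat {
    m <- length(si)
    if (m < 2L) break
    ends <- c(si[-1] - 1L, n)
    same <- which(kinds[-1] == utils::head(kinds, -1))
    drop <- NULL
    for (i in same) {
      a <- si[i]; b <- ends[i + 1L]
      gain <- rss(a, b) -
        (rss(a, si[i + 1L] - 1L) + rss(si[i + 1L], b))
      if (gain < sigma^2 * (z^2 + 2 * log(b - a + 1))) {
        drop <- i + 1L; break
      }
    }
    if (is.null(drop)) break
    si <- si[-drop]; kinds <- kinds[-drop]
  }
  list(si = si, kinds = kinds)
}

# repeatedly absorb the shortest sub-threshold phase into its longer
# neighbor (deterministic tie-breaks: earliest phase, previous neighbor).
# When `y` and `sigma` are given, a short shrinking phase whose slope
# differs from both neighbors by more than `z` standard errors is
# protected: depolymerization is the one process fast enough to produce a
# genuine phase shorter than the minimum duration, so the duration rule
# removes noise flickers without erasing brief collapse runs.
absorb_short_phases <- function(si, kinds, t, min_phase_s, y = NULL,
                                sigma = NULL, z = 3) {
  n <- length(t)
  protected_short <- function(si) {
    m <- length(si)
    if (is.null(y) || is.null(sigma) || m < 2L) return(rep(FALSE, m))
    ends <- c(si[-1] - 1L, n)
    sl <- vapply(seq_len(m), function(i) {
      ix <- si[i]:ends[i]
      tt <- t[ix] - mean(t[ix])
      sxx <- sum(tt * tt)
      if (sxx <= 0) return(c(0, Inf))
      c(sum(tt * y[ix]) / sxx, 1 / sxx)
    }, numeric(2))
    vapply(seq_len(m), function(i) {
      if (sl[1, i] >= 0) return(FALSE)
      nb <- c(if (i > 1L) i - 1L, if (i < m) i + 1L)
      all(vapply(nb, function(j) {
        se <- sigma * sqrt(sl[2, i] + sl[2, j])
        db <- abs(sl[1, i] - sl[1, j])
        is.finite(se) && (se == 0 && db > 1e-12 || se > 0 && db / se >= z)
      }, logical(1)))
    }, logical(1))
  }
  repeat {
    m <- length(si)
    if (m <= 1L) break
    t_start <- t[si]
    t_next <- c(t_start[-1], t[n])
    dur <- t_next - t_start
    short <- which(dur < min_phase_s & !protected_short(si))
    if (length(short) == 0L) break
    i <- short[which.min(dur[short])]
    if (i == 1L) {
      target <- 2L
    } else if (i == m) {
      target <- m - 1L
    } else {
      target <- if (dur[i + 1L] > dur[i - 1L]) i + 1L else i - 1L
    }
    if (target < i) {
      # join previous phase: drop this phase's start
      si <- si[-i]; kinds <- kinds[-i]
    } else {
      # join next phase: next phase now starts where this one did
      si <- si[-(i + 1L)]
      kinds <- kinds[-i]
    }
    mg <- if (is.null(y) || is.null(sigma)) merge_same_kind(si, kinds)
          else merge_same_kind_checked(si, kinds, t, y, sigma, z)
    si <- mg$si; kinds <- mg$kinds
  }
  list(si = si, kinds = kinds)
}

# robust measurement-noise estimate from second differences of the trace
# (slope-free high-pass; MAD-scaled, var of d2 under iid noise is 6 sigma^2)
estimate_noise_sd <- function(y) {
  if (length(y) < 4L) return(0)
  d2 <- diff(y, differences = 2)
  stats::median(abs(d2 - stats::median(d2))) / 0.6745 / sqrt(6)
}

# iteratively remove the boundary whose flanking least-squares slopes are
# least distinguishable (|b1-b2| / (sigma*sqrt(1/sxx1 + 1/sxx2)) below `z`);
# boundaries between genuinely different velocities survive because the
# slope contrast is fixed while the standard error shrinks with span length
prune_boundaries <- function(si, t, y, sigma, z = 3) {
  n <- length(t)
  slope_sxx <- function(a, b) {
    ix <- a:b
    tt <- t[ix] - mean(t[ix])
    sxx <- sum(tt * tt)
    if (sxx <= 0) return(c(0, 0))
    c(sum(tt * y[ix]) / sxx, sxx)
  }
  repeat {
    m <- length(si)
    if (m <= 1L) break
    ends <- c(si[-1] - 1L, n)
    st <- vapply(seq_len(m), function(i) slope_sxx(si[i], ends[i]), numeric(2))
    db <- abs(diff(st[1, ]))
    inv <- ifelse(st[2, ] > 0, 1 / st[2, ], Inf)
    se <- sigma * sqrt(inv[-m] + inv[-1])
    ratio <- ifelse(db < 1e-12, 0,
                    ifelse(!is.finite(se), 0,          # no information: merge
                           ifelse(se > 0, db / se, Inf)))  # exact contrast: keep
    worst <- which.min(ratio)
    if (ratio[worst] >= z) break
    si <- si[-(worst + 1L)]
  }
  si
}

# binary-segmentation split: break any phase at the sample minimizing the
# two-line RSS when the flanking slopes are distinguishable at level `z`
# (same contrast statistic as prune_boundaries); recurses into the halves
split_phases <- function(si, t, y, sigma, z = 3) {
  n <- length(t)
  cs <- function(v) c(0, cumsum(v))
  St <- cs(t); Sy <- cs(y); Stt <- cs(t * t); Sty <- cs(t * y); Syy <- cs(y * y)
  rss_slope <- function(a, b) {
    k <- b - a + 1
    sx <- St[b + 1] - St[a]; sy <- Sy[b + 1] - Sy[a]
    sxx <- Stt[b + 1] - Stt[a]; sxy <- Sty[b + 1] - Sty[a]
    syy <- Syy[b + 1] - Syy[a]
    vxx <- sxx - sx^2 / k
    vxy <- sxy - sx * sy / k
    vyy <- syy - sy^2 / k
    if (vxx <= 0) return(c(vyy, 0, 0))
    c(max(vyy - vxy^2 / vxx, 0), vxy / vxx, vxx)
  }
  # split on residual-sum-of-squares gain: a slope change of size d over
  # spans with curvatures sxx gives an expected gain d^2/(1/sxxL+1/sxxR),
  # so gain >= sigma^2 z^2 matches the prune contrast criterion while
  # also catching sawtooth structure whose half-slopes happen to agree;
  # the 2 log(span) term compensates the search over breakpoints
  split_one <- function(a, b) {
    k <- b - a + 1
    if (k < 4L) return(integer(0))
    cand <- (a + 2L):(b - 1L)
    cost <- vapply(cand, function(j) rss_slope(a, j - 1L)[1] +
                     rss_slope(j, b)[1], numeric(1))
    j <- cand[which.min(cost)]
    gain <- rss_slope(a, b)[1] - cost[j - a - 1L]
    pen <- if (sigma > 0) sigma^2 * (z^2 + 2 * log(k)) else 1e-9
    if (!is.finite(gain) || gain < pen) return(integer(0))
    c(split_one(a, j - 1L), j, split_one(j, b))
  }
  ends <- c(si[-1] - 1L, n)
  extra <- unlist(lapply(seq_along(si), function(i)
    split_one(si[i], ends[i])))
  sort(unique(c(si, extra)))
}

# straight-line RSS of samples a..b in O(1) via shared cumulative sums
make_rss <- function(t, y) {
  cs <- function(z) c(0, cumsum(z))
  St <- cs(t); Sy <- cs(y); Stt <- cs(t * t); Sty <- cs(t * y); Syy <- cs(y * y)
  function(a, b) {
    k <- b - a + 1
    sx <- St[b + 1] - St[a]; sy <- Sy[b + 1] - Sy[a]
    sxx <- Stt[b + 1] - Stt[a]; sxy <- Sty[b + 1] - Sty[a]
    syy <- Syy[b + 1] - Syy[a]
    vxx <- sxx - sx^2 / k
    vxy <- sxy - sx * sy / k
    vyy <- syy - sy^2 / k
    if (vxx <= 0) return(vyy)
    max(vyy - vxy^2 / vxx, 0)
  }
}

# an interior phase only stands if binary segmentation would re-discover
# it: the three-line fit over the phase and its two neighbors must beat a
# single line by twice the split_phases penalty (two breakpoints). Noise
# excursions between two phases at the same level fail this test however
# steep their local slope, because they change nothing across their span
drop_flicker_phases <- function(si, t, y, sigma, z = 3) {
  n <- length(t)
  rss <- make_rss(t, y)
  repeat {
    m <- length(si)
    if (m < 3L || sigma <= 0) return(si)
    ends <- c(si[-1] - 1L, n)
    ratio <- vapply(2:(m - 1L), function(i) {
      a <- si[i - 1L]; b <- ends[i + 1L]
      gain <- rss(a, b) -
        (rss(a, si[i] - 1L) + rss(si[i], ends[i]) + rss(si[i + 1L], b))
      gain / (2 * sigma^2 * (z^2 + 2 * log(b - a + 1)))
    }, numeric(1))
    worst <- which.min(ratio)
    if (ratio[worst] >= 1) return(si)
    si <- si[-c(worst + 1L, worst + 2L)]
  }
}

# move each internal boundary to the sample minimizing the summed RSS of
# straight-line fits on either side (exact search, O(1) RSS via cumsums)
refine_boundaries <- function(si, t, y) {
  n <- length(t)
  m <- length(si)
  if (m < 2L) return(si)
  cs <- function(z) c(0, cumsum(z))
  St <- cs(t); Sy <- cs(y); Stt <- cs(t * t); Sty <- cs(t * y); Syy <- cs(y * y)
  rss <- function(a, b) {
    k <- b - a + 1
    sx <- St[b + 1] - St[a]; sy <- Sy[b + 1] - Sy[a]
    sxx <- Stt[b + 1] - Stt[a]; sxy <- Sty[b + 1] - Sty[a]
    syy <- Syy[b + 1] - Syy[a]
    vxx <- sxx - sx^2 / k
    vxy <- sxy - sx * sy / k
    vyy <- syy - sy^2 / k
    if (vxx <= 0) return(vyy)
    max(vyy - vxy^2 / vxx, 0)
  }
  ends <- c(si[-1] - 1L, n)
  for (b in 2:m) {
    lo <- si[b - 1L] + 2L          # left side keeps >= 2 points
    hi <- ends[b] - 1L             # right side keeps >= 2 points
    if (hi < lo) next
    cand <- lo:hi
    cost <- vapply(cand, function(j) rss(si[b - 1L], j - 1L) + rss(j, ends[b]),
                   numeric(1))
    si[b] <- cand[which.min(cost)]
  }
  si
}

#' Segment many traces
#'
#' Applies [segment_trace()] per `trace_id`, carrying `condition` through.
#'
#' @param traces Tibble with `trace_id`, `condition`, `time_s`,
#'   `length_nm`.
#' @inheritParams segment_trace
#' @return Tibble of phases with `trace_id` and `condition` columns.
#' @export
segment_traces <- function(traces, pause_band_nm_s = 0.3, min_phase_s = 5,
                           window = 5, refine = TRUE) {
  traces |>
    dplyr::group_split(.data$trace_id) |>
    purrr::map(function(g) {
      ph <- segment_trace(g, pause_band_nm_s = pause_band_nm_s,
                          min_phase_s = min_phase_s, window = window,
                          refine = refine)
      ph$trace_id <- g$trace_id[1]
      ph$condition <- if ("condition" %in% names(g)) g$condition[1] else NA
      ph
    }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("trace_id", "condition")
}

#' Dynamic-instability event statistics
#'
#' Catastrophes are growth-or-pause to shrinkage transitions, rescues are
#' shrinkage to growth-or-pause transitions. The catastrophe frequency
#' divides the event count by the total time spent in growth plus pause
#' (a growth-only denominator is available via
#' `cat_denominator = "growth"`); the rescue frequency divides by total
#' shrinkage time and is reported as `NA` with `f_res_defined = FALSE`
#' when no shrinkage time exists. The growth rate is the mean of
#' growth-phase velocities with SEM across phases; pause durations are
#' pooled across traces.
#'
#' @param phases Tibble from [segment_traces()] (needs `trace_id`,
#'   `condition`, `kind`, `duration_s`, `velocity_nm_s`, `t_start`).
#' @param cat_denominator `"growth_pause"` (default) or `"growth"`.
#' @return Tibble with one row per condition: growth rate mean/SEM,
#'   `f_cat`, `f_res`, event counts, pause statistics, time budgets.
#' @export
event_statistics <- function(phases,
                             cat_denominator = c("growth_pause", "growth")) {
  cat_denominator <- match.arg(cat_denominator)
  if (nrow(phases) == 0L) abort("no phases to summarize")
  per_trace <- phases |>
    dplyr::arrange(.data$trace_id, .data$t_start) |>
    dplyr::group_by(.data$condition, .data$trace_id) |>
    dplyr::summarise(
      n_cat = sum(.data$kind[-1] == "shrinkage" &
                    utils::head(.data$kind, -1) != "shrinkage"),
      n_res = sum(.data$kind[-1] != "shrinkage" &
                    utils::head(.data$kind, -1) == "shrinkage"),
      .groups = "drop")

  phases |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_traces = dplyr::n_distinct(.data$trace_id),
      n_growth_phases = sum(.data$kind == "growth"),
      growth_rate_mean = mean(.data$velocity_nm_s[.data$kind == "growth"]),
      growth_rate_sem = sem(.data$velocity_nm_s[.data$kind == "growth"]),
      time_growth_s = sum(.data$duration_s[.data$kind == "growth"]),
      time_pause_s = sum(.data$duration_s[.data$kind == "pause"]),
      time_shrink_s = sum(.data$duration_s[.data$kind == "shrinkage"]),
      pause_mean_s = mean(.data$duration_s[.data$kind == "pause"]),
      pause_sem_s = sem(.data$duration_s[.data$kind == "pause"]),
      n_pauses = sum(.data$kind == "pause"),
      .groups = "drop") |>
    dplyr::left_join(
      per_trace |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(n_cat = sum(.data$n_cat), n_res = sum(.data$n_res),
                         .groups = "drop"),
      by = "condition") |>
    dplyr::mutate(
      cat_time_s = if (cat_denominator == "growth_pause")
        .data$time_growth_s + .data$time_pause_s else .data$time_growth_s,
      f_cat = ifelse(.data$cat_time_s > 0, .data$n_cat / .data$cat_time_s,
                     NA_real_),
      f_res = ifelse(.data$time_shrink_s > 0,
                     .data$n_res / .data$time_shrink_s, NA_real_),
      f_res_defined = .data$time_shrink_s > 0)
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
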