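#' Total-least-squares filament axis
#'
#' Fits a straight axis through 2-D points (math-convention nanometres)
#' by orthogonal regression (first principal component). The rms of the
#' perpendicular residuals and the arclength spanned by the projections
#' are reported.
#'
#' @param points Two-column matrix or data frame of x, y coordinates (nm).
#' @return An object of class `axis_model`: `center`, `direction` (unit,
#'   oriented with positive x, or positive y when vertical), `residual_rms`
#'   (nm), `arclength` (nm), and endpoints `p0`, `p1`.
#' @export
fit_axis <- function(points) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(xy) <- "double"
  if (nrow(xy) < 2L) abort("need at least 2 points to fit an axis")
  if (all(abs(sweep(xy, 2, xy[1, ])) < 1e-12)) {
    abort("coincident points: axis direction undefined")
  }
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2, ctr))
  dir <- sv$v[, 1]
  if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
  proj <- as.numeric(sweep(xy, 2, ctr) %*% dir)
  perp <- as.numeric(sweep(xy, 2, ctr) %*% sv$v[, 2])
  structure(list(
    center = ctr, direction = dir,
    residual_rms = sqrt(mean(perp^2)),
    arclength = diff(range(proj)),
    p0 = ctr + min(proj) * dir,
    p1 = ctr + max(proj) * dir,
    n = nrow(xy)
  ), class = "axis_model")
}

#' Fit axes for every usable filament
#'
#' @param filaments Tibble from [group_filaments()].
#' @return The input with axis columns added: `axis_cx`, `axis_cy`,
#'   `axis_dx`, `axis_dy`, `axis_residual_nm`, `axis_length_nm`.
#' @export
fit_axes <- function(filaments) {
  ax <- purrr::map(seq_len(nrow(filaments)), function(i) {
    if (!filaments$usable[i]) return(NULL)
    fit_axis(filaments$particles[[i]][, c("x_nm", "y_nm")])
  })
  get <- function(f, def = NA_real_) vapply(ax, function(a)
    if (is.null(a)) def else f(a), numeric(1))
  filaments$axis_cx <- get(function(a) a$center[1])
  filaments$axis_cy <- get(function(a) a$center[2])
  filaments$axis_dx <- get(function(a) a$direction[1])
  filaments$axis_dy <- get(function(a) a$direction[2])
  filaments$axis_residual_nm <- get(function(a) a$residual_rms)
  filaments$axis_length_nm <- get(function(a) a$arclength)
  filaments
}

# overlap interval and mean perpendicular distance between two fitted axes;
# distances averaged over sampled points of the shorter axis's overlap
axis_pair_geometry <- function(c1, d1, l1, c2, d2, l2, n_samples = 50) {
  seg_interval <- function(cA, dA, cB, lB_half_dir, lB) {
    # projections of B's endpoints onto A's axis parameter
    pB0 <- sum((cB - lB_half_dir * lB / 2 - cA) * dA)
    pB1 <- sum((cB + lB_half_dir * lB / 2 - cA) * dA)
    sort(c(pB0, pB1))
  }
  # interval of axis 1 parameter covered by itself and by axis 2
  i1 <- c(-l1 / 2, l1 / 2)
  i2 <- seg_interval(c1, d1, c2, d2, l2)
  lo <- max(i1[1], i2[1]); hi <- min(i1[2], i2[2])
  ov1 <- max(0, hi - lo)
  # and symmetrically on axis 2
  j1 <- c(-l2 / 2, l2 / 2)
  j2 <- seg_interval(c2, d2, c1, d1, l1)
  lo2 <- max(j1[1], j2[1]); hi2 <- min(j1[2], j2[2])
  ov2 <- max(0, hi2 - lo2)
  overlap_fraction <- mean(c(ov1, ov2)) / max(min(l1, l2), .Machine$double.eps)
  overlap_fraction <- min(max(overlap_fraction, 0), 1)
  if (ov1 <= 0 || ov2 <= 0) {
    return(list(overlap_fraction = 0, center_distance = NA_real_))
  }
  # sample the shorter axis's overlap region, measure to the other line
  if (l1 <= l2) {
    t <- seq(lo, hi, length.out = n_samples)
    pts <- cbind(c1[1] + t * d1[1], c1[2] + t * d1[2])
    rel <- sweep(pts, 2, c2)
    dist <- abs(rel[, 1] * (-d2[2]) + rel[, 2] * d2[1])
  } else {
    t <- seq(lo2, hi2, length.out = n_samples)
    pts <- cbind(c2[1] + t * d2[1], c2[2] + t * d2[2])
    rel <- sweep(pts, 2, c1)
    dist <- abs(rel[, 1] * (-d1[2]) + rel[, 2] * d1[1])
  }
  list(overlap_fraction = overlap_fraction, center_distance = mean(dist))
}

#' Center and edge distance between two filament axes
#'
#' The center-to-center distance is the mean perpendicular distance from
#' sampled points of the shorter axis's overlap region to the other axis;
#' the edge (wall-to-wall) gap subtracts the filament outer diameter.
#' Negative edge gaps are allowed but indicate overlapping walls.
#'
#' @param a1,a2 `axis_model` objects from [fit_axis()].
#' @param outer_diameter_nm Filament outer diameter (default 25 nm, the
#'   conventional microtubule outer diameter).
#' @param n_samples Sampling density along the overlap (default 50).
#' @return List: `center_distance_nm`, `edge_gap_nm`, `overlap_fraction`,
#'   `overlapping` (logical flag for negative edge gap).
#' @export
gap_distance <- function(a1, a2, outer_diameter_nm = 25, n_samples = 50) {
  stopifnot_scalar_pos(outer_diameter_nm, "outer_diameter_nm")
  g <- axis_pair_geometry(a1$center, a1$direction, a1$arclength,
                          a2$center, a2$direction, a2$arclength,
                          n_samples = n_samples)
  if (g$overlap_fraction <= 0 || !is.finite(g$center_distance)) {
    abort("axes do not overlap: no gap distance defined",
          class = "mtkit_no_overlap")
  }
  edge <- g$center_distance - outer_diameter_nm
  list(center_distance_nm = g$center_distance, edge_gap_nm = edge,
       overlap_fraction = g$overlap_fraction, overlapping = edge < 0)
}

#' Detect candidate bundled pairs per micrograph
#'
#' All unordered pairs of usable filament axes within a micrograph whose
#' wall-to-wall gap and mutual overlap pass the gating thresholds.
#'
#' @param filaments Tibble from [fit_axes()] (optionally after
#'   [filament_polarity()]).
#' @param max_edge_gap_nm Maximum edge gap to call a pair bundled
#'   (default 50 nm).
#' @param min_overlap_frac Minimum mutual overlap fraction (default 0.5).
#' @param outer_diameter_nm Filament outer diameter (default 25 nm).
#' @return Tibble of pairs: micrograph, tube ids `tube_a < tube_b`,
#'   `center_distance_nm`, `edge_gap_nm`, `overlap_fraction`,
#'   `overlapping`.
#' @export
find_pairs <- function(filaments, max_edge_gap_nm = 50,
                       min_overlap_frac = 0.5, outer_diameter_nm = 25) {
  fl <- filaments[filaments$usable & is.finite(filaments$axis_dx), ,
                  drop = FALSE]
  out <- fl |>
    dplyr::group_split(.data$micrograph_id) |>
    purrr::map(function(g) {
      n <- nrow(g)
      if (n < 2L) return(NULL)
      res <- list()
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        geo <- axis_pair_geometry(
          c(g$axis_cx[i], g$axis_cy[i]), c(g$axis_dx[i], g$axis_dy[i]),
          g$axis_length_nm[i],
          c(g$axis_cx[j], g$axis_cy[j]), c(g$axis_dx[j], g$axis_dy[j]),
          g$axis_length_nm[j])
        if (geo$overlap_fraction < min_overlap_frac) next
        edge <- geo$center_distance - outer_diameter_nm
        if (!is.finite(edge) || edge > max_edge_gap_nm) next
        res[[length(res) + 1L]] <- tibble::tibble(
          micrograph_id = g$micrograph_id[i],
          tube_a = min(g$tube_id[i], g$tube_id[j]),
          tube_b = max(g$tube_id[i], g$tube_id[j]),
          center_distance_nm = geo$center_distance,
          edge_gap_nm = edge,
          overlap_fraction = geo$overlap_fraction,
          overlapping = edge < 0)
      }
      dplyr::bind_rows(res)
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0L) {
    out <- tibble::tibble(micrograph_id = character(0), tube_a = integer(0),
                          tube_b = integer(0), center_distance_nm = numeric(0),
                          edge_gap_nm = numeric(0),
                          overlap_fraction = numeric(0),
                          overlapping = logical(0))
  }
  out
}

#' Classify a polarity pair as parallel or antiparallel
#'
#' The angle between the two plus-end unit vectors is arccos of their dot
#' product; below 90 degrees the pair is parallel, above antiparallel, and
#' within `tie_tol_deg` of 90 it is flagged ambiguous.
#'
#' @param angle1_deg,angle2_deg Consensus polarity angles in degrees.
#' @param tie_tol_deg Half-width of the ambiguous band around 90 degrees
#'   (default 1).
#' @return List: `angle_between_deg` in \[0, 180\], `orientation_class`
#'   in `parallel`/`antiparallel`/`ambiguous`.
#' @export
classify_pair <- function(angle1_deg, angle2_deg, tie_tol_deg = 1) {
  d <- abs(wrap_angle(angle2_deg - angle1_deg))
  ang <- d  # |wrapped difference| is already in [0, 180]
  cls <- if (abs(ang - 90) <= tie_tol_deg) "ambiguous"
         else if (ang < 90) "parallel" else "antiparallel"
  list(angle_between_deg = ang, orientation_class = cls)
}

#' Attach orientation classes to detected pairs
#'
#' Joins per-filament consensus polarity onto a pair table and classifies
#' each pair. Pairs with a non-confident member are retained with class
#' `NA` and an exclusion reason.
#'
#' @param pairs Tibble from [find_pairs()].
#' @param filaments Tibble from [filament_polarity()].
#' @param tie_tol_deg Ambiguity band around 90 degrees (default 1).
#' @return `pairs` with `angle_between_deg`, `orientation_class`,
#'   `excluded_reason` added.
#' @export
classify_pairs <- function(pairs, filaments, tie_tol_deg = 1) {
  key <- paste(filaments$micrograph_id, filaments$tube_id)
  ia <- match(paste(pairs$micrograph_id, pairs$tube_a), key)
  ib <- match(paste(pairs$micrograph_id, pairs$tube_b), key)
  ang <- rep(NA_real_, nrow(pairs))
  cls <- rep(NA_character_, nrow(pairs))
  reason <- rep(NA_character_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (is.na(ia[k]) || is.na(ib[k])) { reason[k] <- "missing filament"; next }
    ok <- isTRUE(filaments$confident[ia[k]]) &&
      isTRUE(filaments$confident[ib[k]])
    if (!ok) { reason[k] <- "low-coherence polarity"; next }
    cc <- classify_pair(filaments$angle_deg[ia[k]], filaments$angle_deg[ib[k]],
                        tie_tol_deg = tie_tol_deg)
    ang[k] <- cc$angle_between_deg
    cls[k] <- cc$orientation_class
  }
  pairs$angle_between_deg <- ang
  pairs$orientation_class <- cls
  pairs$excluded_reason <- reason
  pairs
}

#' Summarize a set of classified bundle pairs
#'
#' Counts per orientation class, the parallel fraction (ambiguous pairs
#' excluded), an exact two-sided binomial test of the parallel count
#' against an even split, and wall-to-wall gap statistics with a
#' fixed-width histogram.
#'
#' @param pairs Tibble from [classify_pairs()].
#' @param bin_width_nm Histogram bin width for the edge gap (default 1 nm).
#' @return Object of class `bundle_summary` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
bundle_summary <- function(pairs, bin_width_nm = 1) {
  cl <- pairs$orientation_class[!is.na(pairs$orientation_class)]
  if (length(cl) == 0L) abort("no classified pairs to summarize")
  n_par <- sum(cl == "parallel")
  n_anti <- sum(cl == "antiparallel")
  n_amb <- sum(cl == "ambiguous")
  bt <- if (n_par + n_anti > 0)
    stats::binom.test(n_par, n_par + n_anti, p = 0.5)$p.value else NA_real_
  gaps <- pairs$edge_gap_nm[!is.na(pairs$orientation_class)]
  brk <- seq(floor(min(gaps) / bin_width_nm) * bin_width_nm,
             ceiling(max(gaps) / bin_width_nm) * bin_width_nm + bin_width_nm,
             by = bin_width_nm)
  h <- graphics::hist(gaps, breaks = brk, plot = FALSE)
  structure(list(
    n_total = n_par + n_anti + n_amb,
    n_parallel = n_par, n_antiparallel = n_anti, n_ambiguous = n_amb,
    fraction_parallel = if (n_par + n_anti > 0) n_par / (n_par + n_anti)
                        else NA_real_,
    binomial_p = bt,
    gap_min_nm = min(gaps), gap_max_nm = max(gaps),
    gap_mean_nm = mean(gaps),
    gap_sd_nm = if (length(gaps) >= 2) stats::sd(gaps) else NA_real_,
    histogram = tibble::tibble(bin_lo_nm = utils::head(h$breaks, -1),
                               bin_hi_nm = h$breaks[-1], count = h$counts)
  ), class = "bundle_summary")
}

#' @export
print.bundle_summary <- function(x, ...) {
  cat(sprintf(
    "Bundle summary: %d pairs (%d parallel, %d antiparallel, %d ambiguous)\n",
    x$n_total, x$n_parallel, x$n_antiparallel, x$n_ambiguous))
  cat(sprintf("  fraction parallel %.3f (exact binomial p = %.4g vs 0.5)\n",
              x$fraction_parallel, x$binomial_p))
  cat(sprintf("  edge gap [nm]: min %.3f, max %.3f, mean %.3f, sd %.3f\n",
              x$gap_min_nm, x$gap_max_nm, x$gap_mean_nm, x$gap_sd_nm))
  invisible(x)
}

#' @export
tidy.bundle_summary <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total, n_parallel = x$n_parallel,
    n_antiparallel = x$n_antiparallel, n_ambiguous = x$n_ambiguous,
    fraction_parallel = x$fraction_parallel, binomial_p = x$binomial_p,
    gap_min_nm = x$gap_min_nm, gap_max_nm = x$gap_max_nm,
    gap_mean_nm = x$gap_mean_nm, gap_sd_nm = x$gap_sd_nm)
}

#' @export
glance.bundle_summary <- function(x, ...) tidy.bundle_summary(x)

#' Axial dimer-rise comparison
#'
#' Difference between a reference and an observed axial dimer rise along a
#' protofilament; positive values are lattice compaction.
#'
#' @param rise_ref_A,rise_obs_A Dimer rises in Angstrom (both > 0).
#' @return Tibble: `rise_ref_A`, `rise_obs_A`, `delta_A` (0.01 A
#'   precision), `delta_display` (1-decimal string).
#' @export
dimer_rise_delta <- function(rise_ref_A, rise_obs_A) {
  stopifnot_scalar_pos(rise_ref_A, "rise_ref_A")
  stopifnot_scalar_pos(rise_obs_A, "rise_obs_A")
  d <- round(rise_ref_A - rise_obs_A, 2)
  tibble::tibble(rise_ref_A = rise_ref_A, rise_obs_A = rise_obs_A,
                 delta_A = d, delta_display = sprintf("%.1f", d))
}

#' Full polarity-and-bundling pipeline over a particle table
#'
#' Convenience wrapper chaining [group_filaments()], [fit_axes()],
#' [filament_polarity()], [find_pairs()], [classify_pairs()] and
#' [bundle_summary()].
#'
#' @param particles Tibble from [read_particles()].
#' @param config Configuration list from [mt_config()].
#' @return List: `filaments`, `pairs`, `summary`.
#' @export
trace_bundles <- function(particles, config = mt_config()) {
  filaments <- particles |>
    group_filaments() |>
    fit_axes() |>
    filament_polarity(coherence_threshold = config$coherence_threshold,
                      min_sin_tilt = config$min_sin_tilt)
  pairs <- filaments |>
    find_pairs(max_edge_gap_nm = config$max_edge_gap_nm,
               min_overlap_frac = config$min_overlap_frac,
               outer_diameter_nm = config$mt_outer_diameter_nm) |>
    classify_pairs(filaments, tie_tol_deg = config$tie_tol_deg)
  list(filaments = filaments, pairs = pairs,
       summary = if (any(!is.na(pairs$orientation_class)))
         bundle_summary(pairs) else NULL)
}
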