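#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_rect labs theme_minimal facet_wrap scale_x_log10
NULL

#' Plot an isotherm fit
#'
#' Points are the observed fractions, the line is the pooled fitted
#' curve on a log concentration axis.
#'
#' @param object `isotherm_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.isotherm_fit <- function(object, ...) {
  d <- object$data
  L <- exp(seq(log(min(d$concentration_uM)), log(max(d$concentration_uM)),
               length.out = 200))
  curve <- tibble::tibble(
    concentration_uM = L,
    fraction_bound = isotherm_fraction(L, object$pooled$kd,
                                       object$pooled$bmax,
                                       model = object$model,
                                       probe_uM = object$probe_uM))
  ggplot(d, aes(x = .data$concentration_uM, y = .data$fraction_bound)) +
    geom_point(aes(shape = factor(.data$replicate)), alpha = 0.8) +
    geom_line(data = curve, colour = "steelblue") +
    scale_x_log10() +
    labs(x = "ligand concentration (µM)", y = "fraction bound",
         shape = "replicate",
         title = sprintf("Kd = %.3g µM (pooled fit)", object$pooled$kd)) +
    theme_minimal()
}

#' Plot a bundle summary
#'
#' Histogram of wall-to-wall gaps with the class counts in the title.
#'
#' @param object `bundle_summary` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bundle_summary <- function(object, ...) {
  h <- object$histogram
  ggplot(h, aes(x = (.data$bin_lo_nm + .data$bin_hi_nm) / 2,
                y = .data$count)) +
    geom_col(fill = "grey40", width = h$bin_hi_nm[1] - h$bin_lo_nm[1]) +
    labs(x = "edge gap (nm)", y = "pairs",
         title = sprintf("%d pairs: %d parallel / %d antiparallel",
                         object$n_total, object$n_parallel,
                         object$n_antiparallel)) +
    theme_minimal()
}

#' Plot a segmented trace
#'
#' Length-vs-time with phases shaded by kind.
#'
#' @param trace Tibble with `time_s`, `length_nm`.
#' @param phases Tibble from [segment_trace()].
#' @return A ggplot.
#' @export
plot_trace_phases <- function(trace, phases) {
  ggplot(trace, aes(x = .data$time_s, y = .data$length_nm)) +
    geom_rect(data = phases, inherit.aes = FALSE,
              aes(xmin = .data$t_start, xmax = .data$t_end,
                  ymin = -Inf, ymax = Inf, fill = .data$kind),
              alpha = 0.2) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "length (nm)", fill = "phase") +
    theme_minimal()
}

#' Plot polarity arrows
#'
#' Arrow overlay in image-pixel coordinates (y axis reversed to match the
#' micrograph convention); non-confident filaments are drawn dashed.
#'
#' @param arrows Tibble from [polarity_arrows()].
#' @return A ggplot.
#' @export
plot_arrows <- function(arrows) {
  ggplot(arrows) +
    ggplot2::geom_segment(
      aes(x = .data$anchor_x, y = .data$anchor_y,
          xend = .data$tip_x, yend = .data$tip_y,
          linetype = !.data$confident),
      arrow = grid::arrow(length = grid::unit(4, "pt")),
      colour = "cyan4", show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    facet_wrap(~micrograph_id) +
    labs(x = "x (px)", y = "y (px)") +
    theme_minimal()
}
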