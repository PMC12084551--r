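#' In-plane plus-end direction from Euler angles
#'
#' Under the ZYZ convention A = Rz(psi) Ry(tilt) Rz(rot) with the plus end
#' along the reference +z axis, the in-plane projection of the filament
#' direction is (sin tilt cos psi, sin tilt sin psi): the unit direction
#' depends only on psi, and sin(tilt) measures how much of the axis lies
#' in the plane, so it is used as a reliability weight. Segments viewed
#' nearly end-on (sin tilt below `min_sin_tilt`) carry no usable in-plane
#' direction and are flagged undefined.
#'
#' @param rot_deg,tilt_deg,psi_deg Euler angles in degrees (vectorized).
#'   `tilt_deg` must lie in \[0, 180\]; `rot_deg` does not affect the
#'   result but is accepted for a uniform interface.
#' @param min_sin_tilt Threshold on sin(tilt) below which the direction is
#'   flagged undefined (default 0.1).
#' @return Tibble with unit components `ux`, `uy` (math convention, y up),
#'   `weight` = sin(tilt) clamped to \[0, 1\], and logical `defined`.
#' @export
plane_direction <- function(rot_deg, tilt_deg, psi_deg, min_sin_tilt = 0.1) {
  if (any(tilt_deg < 0 | tilt_deg > 180)) {
    abort("tilt_deg must lie in [0, 180]")
  }
  st <- sin(deg2rad(tilt_deg))
  tibble::tibble(
    ux = cos(deg2rad(psi_deg)),
    uy = sin(deg2rad(psi_deg)),
    weight = pmin(pmax(st, 0), 1),
    defined = st >= min_sin_tilt
  )
}

#' Consensus direction of a set of weighted in-plane vectors
#'
#' Combines per-segment direction angles into one filament polarity by a
#' weighted circular mean after a global two-orientation test: the raw
#' assignment is compared with the assignment in which every vector is
#' flipped by 180 degrees onto the side of the doubled-angle (axial) mean
#' it is closer to, and the assignment with the larger weighted mean
#' resultant length wins. The consensus is reported in the majority
#' orientation; `n_flipped` counts vectors flipped against it.
#'
#' @param angle_deg Direction angles in degrees.
#' @param weight Non-negative weights (default 1).
#' @param coherence_threshold Mean resultant length above which the
#'   consensus is marked confident (default 0.8).
#' @return A list: `angle_deg` in \[-180, 180), `coherence` in \[0, 1\],
#'   `n_used`, `n_flipped`, `confident`, and `tie` (equal-weight split
#'   between the two orientations, resolved toward \[0, 180)).
#' @export
consensus_direction <- function(angle_deg, weight = rep(1, length(angle_deg)),
                                coherence_threshold = 0.8) {
  keep <- is.finite(angle_deg) & is.finite(weight) & weight > 0
  angle_deg <- angle_deg[keep]
  weight <- weight[keep]
  n <- length(angle_deg)
  if (n == 0L) abort("no usable directions", class = "mtkit_no_directions")
  th <- deg2rad(angle_deg)
  W <- sum(weight)
  ux <- cos(th); uy <- sin(th)

  # orientation 1: raw weighted circular mean
  rx <- sum(weight * ux); ry <- sum(weight * uy)
  R_raw <- sqrt(rx^2 + ry^2) / W

  # orientation 2: flip each vector onto the nearer side of the axial mean
  phi <- atan2(sum(weight * sin(2 * th)), sum(weight * cos(2 * th))) / 2
  s <- ifelse(cos(th - phi) >= 0, 1, -1)
  fx <- sum(weight * s * ux); fy <- sum(weight * s * uy)
  R_flip <- sqrt(fx^2 + fy^2) / W

  tie <- FALSE
  if (R_flip > R_raw + 1e-12) {
    net <- sum(weight * s)
    if (abs(net) < 1e-9) {
      # equal weight on both orientations: deterministically pick the
      # orientation whose angle lies in [0, 180)
      tie <- TRUE
      ang <- rad2deg(atan2(fy, fx))
      if (wrap_angle(ang) < 0) s <- -s
    } else if (net < 0) {
      s <- -s
    }
    fx <- sum(weight * s * ux); fy <- sum(weight * s * uy)
    ang <- rad2deg(atan2(fy, fx))
    coh <- sqrt(fx^2 + fy^2) / W
    n_flipped <- sum(s < 0)
  } else {
    ang <- rad2deg(atan2(ry, rx))
    coh <- R_raw
    n_flipped <- 0L
  }
  list(angle_deg = wrap_angle(ang), coherence = coh, n_used = n,
       n_flipped = as.integer(n_flipped),
       confident = coh >= coherence_threshold, tie = tie)
}

#' Per-filament consensus polarity
#'
#' Applies [plane_direction()] to every particle of every filament and
#' reduces each filament to a consensus polarity via
#' [consensus_direction()]. Filaments with fewer than two defined
#' directions get `NA` polarity and are never confident.
#'
#' @param filaments Tibble from [group_filaments()].
#' @param coherence_threshold Confidence threshold on the weighted mean
#'   resultant length (default 0.8).
#' @param min_sin_tilt Near-end-on exclusion threshold (default 0.1).
#' @return The input with columns `angle_deg`, `coherence`, `n_used`,
#'   `n_flipped`, `confident` added.
#' @export
filament_polarity <- function(filaments, coherence_threshold = 0.8,
                              min_sin_tilt = 0.1) {
  res <- purrr::map(filaments$particles, function(df) {
    if (nrow(df) < 2L) {
      return(list(angle_deg = NA_real_, coherence = NA_real_, n_used = 0L,
                  n_flipped = NA_integer_, confident = FALSE))
    }
    pd <- plane_direction(df$rot_deg, df$tilt_deg, df$psi_deg,
                          min_sin_tilt = min_sin_tilt)
    pd <- pd[pd$defined, , drop = FALSE]
    if (nrow(pd) < 2L) {
      return(list(angle_deg = NA_real_, coherence = NA_real_, n_used = 0L,
                  n_flipped = NA_integer_, confident = FALSE))
    }
    consensus_direction(rad2deg(atan2(pd$uy, pd$ux)), pd$weight,
                        coherence_threshold = coherence_threshold)
  })
  filaments$angle_deg <- vapply(res, `[[`, numeric(1), "angle_deg")
  filaments$coherence <- vapply(res, `[[`, numeric(1), "coherence")
  filaments$n_used <- vapply(res, `[[`, integer(1), "n_used")
  filaments$n_flipped <- vapply(res, `[[`, integer(1), "n_flipped")
  filaments$confident <- vapply(res, `[[`, logical(1), "confident")
  filaments
}

#' Minus-to-plus arrow overlay records
#'
#' One arrow per filament, anchored at the fitted axis midpoint and
#' pointing along the consensus polarity. Anchors and tips are reported in
#' image-convention pixels (the y axis is flipped once when leaving the
#' internal math frame). Filaments without confident polarity are kept
#' but flagged `low_coherence`.
#'
#' @param filaments Tibble from [filament_polarity()] (axis columns from
#'   [fit_axes()] are used when present, else the particle centroid).
#' @param arrow_len_px Arrow length in pixels (default 50).
#' @return Tibble: `micrograph_id`, `tube_id`, `anchor_x`, `anchor_y`,
#'   `tip_x`, `tip_y`, `coherence`, `confident`.
#' @export
polarity_arrows <- function(filaments, arrow_len_px = 50) {
  stopifnot_scalar_pos(arrow_len_px, "arrow_len_px")
  fl <- filaments[!is.na(filaments$angle_deg), , drop = FALSE]
  if (nrow(fl) == 0L) {
    return(tibble::tibble(micrograph_id = character(0), tube_id = integer(0),
                          anchor_x = numeric(0), anchor_y = numeric(0),
                          tip_x = numeric(0), tip_y = numeric(0),
                          coherence = numeric(0), confident = logical(0)))
  }
  mid <- purrr::map(seq_len(nrow(fl)), function(i) {
    df <- fl$particles[[i]]
    px <- df$pixel_size_A[1]
    if (all(c("axis_cx", "axis_cy") %in% names(fl))) {
      nm_to_px(fl$axis_cx[i], fl$axis_cy[i], px)
    } else {
      nm_to_px(mean(df$x_nm), mean(df$y_nm), px)
    }
  })
  ax <- vapply(mid, `[[`, numeric(1), "x_px")
  ay <- vapply(mid, `[[`, numeric(1), "y_px")
  ang <- deg2rad(fl$angle_deg)
  # direction is math-convention; the image tip offset flips y
  tibble::tibble(
    micrograph_id = fl$micrograph_id,
    tube_id = fl$tube_id,
    anchor_x = ax, anchor_y = ay,
    tip_x = ax + arrow_len_px * cos(ang),
    tip_y = ay - arrow_len_px * sin(ang),
    coherence = fl$coherence,
    confident = fl$confident
  )
}

#' Write an arrow overlay as SVG
#'
#' Minimal standalone SVG with one line-with-head per arrow; arrows from
#' non-confident filaments are drawn dashed.
#'
#' @param arrows Tibble from [polarity_arrows()].
#' @param path Output file path.
#' @param width,height Canvas size in pixels (defaults cover the arrows).
#' @return `path`, invisibly.
#' @export
write_arrow_svg <- function(arrows, path, width = NULL, height = NULL) {
  pad <- 60
  if (is.null(width)) width <- ceiling(max(c(arrows$anchor_x, arrows$tip_x, 1)) + pad)
  if (is.null(height)) height <- ceiling(max(c(arrows$anchor_y, arrows$tip_y, 1)) + pad)
  hdr <- sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                        'width="%d" height="%d">'), width, height)
  defs <- paste0('<defs><marker id="head" orient="auto" markerWidth="6" ',
                 'markerHeight="6" refX="5" refY="3">',
                 '<path d="M0,0 L6,3 L0,6 z" fill="cyan"/></marker></defs>')
  lines <- character(nrow(arrows))
  for (i in seq_len(nrow(arrows))) {
    dash <- if (isTRUE(arrows$confident[i])) "" else ' stroke-dasharray="4,3"'
    lines[i] <- sprintf(
      '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="cyan" stroke-width="2" marker-end="url(#head)"%s/>',
      arrows$anchor_x[i], arrows$anchor_y[i],
      arrows$tip_x[i], arrows$tip_y[i], dash)
  }
  writeLines(c(hdr, defs, lines, "</svg>"), path)
  invisible(path)
}
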