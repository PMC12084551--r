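#' Read a RELION-style particle STAR file
#'
#' Parses the particles `loop_` block of a STAR file (either the flat
#' RELION 3.0 dialect or the 3.1 dialect with a separate `data_optics`
#' block) into a tibble with one row per helical segment. Canonical
#' columns are renamed to plain identifiers; all other STAR columns are
#' retained verbatim so that [write_particles()] can round-trip them.
#'
#' Canonical columns and their STAR sources:
#' \describe{
#'   \item{micrograph_id}{`rlnMicrographName`}
#'   \item{x_px, y_px}{`rlnCoordinateX`, `rlnCoordinateY` (image
#'     convention: origin top-left, y increasing downward)}
#'   \item{rot_deg, tilt_deg, psi_deg}{`rlnAngleRot`, `rlnAngleTilt`,
#'     `rlnAnglePsi`; rot and psi are reduced to \[-180, 180), tilt must
#'     lie in \[0, 180\]}
#'   \item{tube_id}{`rlnHelicalTubeID`}
#'   \item{pixel_size_A}{`rlnImagePixelSize`, taken per record, else from
#'     the optics group, else from `pixel_size_A`}
#' }
#'
#' @param source Path to a STAR file, or a character vector of STAR text
#'   (anything containing a newline is treated as text).
#' @param pixel_size_A Fallback pixel size in Angstrom per pixel, used when
#'   the file carries none. Default 0.83.
#' @return A tibble of particle records (class `mt_particles`).
#' @seealso [write_particles()], [group_filaments()]
#' @export
read_particles <- function(source, pixel_size_A = NULL) {
  blocks <- star_parse_blocks(star_source_lines(source))
  req <- c("rlnMicrographName", "rlnCoordinateX", "rlnCoordinateY",
           "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi", "rlnHelicalTubeID")
  part_idx <- which(vapply(blocks, function(b) all(req %in% names(b$table)) ||
                             "rlnCoordinateX" %in% names(b$table), logical(1)))
  if (length(part_idx) == 0L) {
    abort("no particles loop_ block found in STAR source")
  }
  part <- blocks[[part_idx[1]]]$table
  missing <- setdiff(req, names(part))
  if (length(missing) > 0L) {
    abort(sprintf("missing column%s in particles block: %s",
                  if (length(missing) > 1L) "s" else "",
                  paste(missing, collapse = ", ")),
          class = "mtkit_missing_column")
  }

  num_cols <- c("rlnCoordinateX", "rlnCoordinateY", "rlnAngleRot",
                "rlnAngleTilt", "rlnAnglePsi", "rlnHelicalTubeID")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(part[[cc]]))
    bad <- which(is.na(v) & !is.na(part[[cc]]))
    if (length(bad) > 0L) {
      abort(sprintf("malformed numeric value in column %s at data row %d: '%s'",
                    cc, bad[1], part[[cc]][bad[1]]),
            class = "mtkit_malformed_cell")
    }
    part[[cc]] <- v
  }

  # pixel size: per-record column > optics group > argument > default
  px <- NULL
  if ("rlnImagePixelSize" %in% names(part)) {
    px <- suppressWarnings(as.numeric(part[["rlnImagePixelSize"]]))
  } else {
    opt_idx <- which(vapply(blocks, function(b)
      all(c("rlnOpticsGroup", "rlnImagePixelSize") %in% names(b$table)) &&
        !"rlnCoordinateX" %in% names(b$table), logical(1)))
    if (length(opt_idx) > 0L && "rlnOpticsGroup" %in% names(part)) {
      opt <- blocks[[opt_idx[1]]]$table
      key <- match(as.numeric(part[["rlnOpticsGroup"]]),
                   as.numeric(opt[["rlnOpticsGroup"]]))
      px <- as.numeric(opt[["rlnImagePixelSize"]])[key]
    }
  }
  if (is.null(px)) px <- rep(if (is.null(pixel_size_A)) 0.83 else pixel_size_A,
                             nrow(part))
  if (any(!is.finite(px) | px <= 0)) abort("pixel_size_A must be > 0")

  tilt <- part[["rlnAngleTilt"]]
  if (any(tilt < 0 | tilt > 180)) {
    abort("rlnAngleTilt outside [0, 180]", class = "mtkit_bad_angle")
  }

  extra <- setdiff(names(part), c(req, "rlnImagePixelSize"))
  out <- tibble::tibble(
    micrograph_id = as.character(part[["rlnMicrographName"]]),
    x_px = part[["rlnCoordinateX"]],
    y_px = part[["rlnCoordinateY"]],
    rot_deg = wrap_angle(part[["rlnAngleRot"]]),
    tilt_deg = tilt,
    psi_deg = wrap_angle(part[["rlnAnglePsi"]]),
    tube_id = as.integer(part[["rlnHelicalTubeID"]]),
    pixel_size_A = px
  )
  for (cc in extra) out[[cc]] <- part[[cc]]
  class(out) <- c("mt_particles", class(out))
  out
}

#' Write particle records as STAR text
#'
#' Emits a flat `data_particles` loop readable by [read_particles()];
#' canonical columns are written under their RELION names and any extra
#' columns are re-emitted verbatim, so read-write-read is value-identical
#' on the required columns.
#'
#' @param table A tibble as returned by [read_particles()] (canonical
#'   column names).
#' @param path Optional file path; when `NULL` the STAR text is returned
#'   as a character scalar.
#' @return The STAR text, invisibly when written to `path`.
#' @export
write_particles <- function(table, path = NULL) {
  canon <- c(micrograph_id = "rlnMicrographName",
             x_px = "rlnCoordinateX", y_px = "rlnCoordinateY",
             rot_deg = "rlnAngleRot", tilt_deg = "rlnAngleTilt",
             psi_deg = "rlnAnglePsi", tube_id = "rlnHelicalTubeID",
             pixel_size_A = "rlnImagePixelSize")
  missing <- setdiff(setdiff(names(canon), "pixel_size_A"), names(table))
  if (length(missing) > 0L) {
    abort(sprintf("table lacks canonical column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  cols <- intersect(names(canon), names(table))
  star_names <- unname(canon[cols])
  extra <- setdiff(names(table), names(canon))
  all_names <- c(star_names, extra)

  fmt_col <- function(v) {
    if (is.numeric(v)) {
      out <- formatC(v, format = "g", digits = 15)
      out[v == round(v) & abs(v) < 1e15] <-
        formatC(v[v == round(v) & abs(v) < 1e15], format = "d")
      out
    } else {
      as.character(v)
    }
  }
  body_cols <- c(lapply(table[cols], fmt_col), lapply(table[extra], fmt_col))
  header <- c("", "data_particles", "", "loop_",
              sprintf("_%s #%d", all_names, seq_along(all_names)))
  rows <- if (nrow(table) == 0L) character(0) else
    do.call(paste, c(body_cols, list(sep = "\t")))
  txt <- paste(c(header, rows, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Group particles into per-filament traces
#'
#' Partitions a particle table by `(micrograph_id, tube_id)` and orders
#' the particles of each filament by their projection onto the filament's
#' principal axis (total least squares, in the internal math-convention
#' nanometre frame). Filaments with fewer than two particles are flagged
#' untraceable and excluded from downstream geometry, with a warning.
#'
#' @param particles Tibble from [read_particles()].
#' @return A tibble with one row per filament: `micrograph_id`, `tube_id`,
#'   `n_particles`, `usable`, and a list-column `particles` of ordered
#'   particle tibbles carrying `x_nm`/`y_nm` coordinates.
#' @export
group_filaments <- function(particles) {
  if (nrow(particles) == 0L) abort("particle table is empty")
  nm <- px_to_nm(particles$x_px, particles$y_px, particles$pixel_size_A)
  particles$x_nm <- nm$x_nm
  particles$y_nm <- nm$y_nm

  out <- particles |>
    dplyr::group_by(.data$micrograph_id, .data$tube_id) |>
    tidyr::nest(particles = -c("micrograph_id", "tube_id")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      n_particles = vapply(.data$particles, nrow, integer(1)),
      usable = .data$n_particles >= 2L,
      particles = purrr::map(.data$particles, order_along_axis)
    ) |>
    dplyr::arrange(.data$micrograph_id, .data$tube_id)
  n_bad <- sum(!out$usable)
  if (n_bad > 0L) {
    warn(sprintf("%d filament(s) with <2 particles flagged untraceable", n_bad))
  }
  class(out) <- c("mt_filaments", class(out))
  out
}

# order particles of one filament by projection on the principal axis
order_along_axis <- function(df) {
  if (nrow(df) < 2L) return(df)
  xy <- cbind(df$x_nm, df$y_nm)
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2, ctr))
  proj <- as.numeric(sweep(xy, 2, ctr) %*% sv$v[, 1])
  # orient deterministically so ordering is row-order invariant
  if (sv$v[1, 1] < 0 || (sv$v[1, 1] == 0 && sv$v[2, 1] < 0)) proj <- -proj
  df[order(proj, df$x_nm, df$y_nm), , drop = FALSE]
}

# ---- low-level STAR text handling -----------------------------------------

star_source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
}

# Parse every data_ block containing a loop_ into a character data frame.
star_parse_blocks <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  starts <- grep("^data_", lines)
  if (length(starts) == 0L) abort("no data_ block found in STAR source")
  ends <- c(starts[-1] - 1L, length(lines))
  blocks <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    name <- sub("^data_", "", chunk[1])
    loop_at <- which(chunk == "loop_")
    if (length(loop_at) == 0L) next
    body <- chunk[(loop_at[1] + 1L):length(chunk)]
    body <- body[nzchar(body)]
    hdr <- grep("^_", body)
    if (length(hdr) == 0L) next
    col_names <- sub("^_([^ \t]+).*$", "\\1", body[hdr])
    data_lines <- body[setdiff(seq_along(body), hdr)]
    data_lines <- data_lines[!grepl("^data_|^loop_", data_lines)]
    fields <- strsplit(data_lines, "[ \t]+")
    nc <- length(col_names)
    ok <- vapply(fields, length, integer(1)) == nc
    if (any(!ok)) {
      abort(sprintf("STAR block '%s': row %d has %d fields, expected %d",
                    name, which(!ok)[1],
                    length(fields[[which(!ok)[1]]]), nc))
    }
    tab <- if (length(fields) == 0L) {
      stats::setNames(as.data.frame(matrix(character(0), ncol = nc),
                                    stringsAsFactors = FALSE), col_names)
    } else {
      stats::setNames(as.data.frame(do.call(rbind, fields),
                                    stringsAsFactors = FALSE), col_names)
    }
    blocks[[length(blocks) + 1L]] <- list(name = name, table = tab)
  }
  if (length(blocks) == 0L) abort("no loop_ block found in STAR source")
  blocks
}
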