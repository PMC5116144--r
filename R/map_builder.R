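#' Single-isotope elemental map
#'
#' A 2D intensity matrix in image orientation (rows correspond to
#' `y_coords`, columns to `x_coords`) with uniformly spaced physical axes in
#' micrometres. Normalized maps hold dimensionless analyte/standard ratios.
#'
#' @param values numeric matrix, `length(y_coords)` rows and
#'   `length(x_coords)` columns.
#' @param x_coords,y_coords uniformly spaced axis coordinates in micrometres.
#' @param isotope isotope label (any accepted spelling).
#' @param normalized logical; is this a ratio map?
#' @param standard standard isotope label when `normalized`.
#' @return an object of class `elemental_map`.
#' @export
elemental_map <- function(values, x_coords, y_coords, isotope,
                          normalized = FALSE, standard = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(y_coords) || ncol(values) != length(x_coords)) {
    stop("matrix is ", nrow(values), "x", ncol(values),
         " but axes have ", length(y_coords), " y and ", length(x_coords),
         " x coordinates", call. = FALSE)
  }
  for (ax in list(x_coords, y_coords)) {
    if (length(ax) > 2L && diff(range(diff(ax))) > 1e-9 * max(abs(ax), 1)) {
      stop("axis coordinates must be uniformly spaced", call. = FALSE)
    }
  }
  structure(list(values = values,
                 x_coords = as.numeric(x_coords),
                 y_coords = as.numeric(y_coords),
                 isotope = isotope_canonical(isotope),
                 normalized = isTRUE(normalized),
                 standard = if (is.null(standard)) NULL
                            else isotope_canonical(standard)),
            class = "elemental_map")
}

#' @export
print.elemental_map <- function(x, ...) {
  cat("<elemental_map> ", x$isotope, ": ", nrow(x$values), " x ",
      ncol(x$values), " cells",
      if (x$normalized) paste0(", normalized by ", x$standard) else "",
      "\n  x: ", min(x$x_coords), "..", max(x$x_coords), " um",
      "  y: ", min(x$y_coords), "..", max(x$y_coords), " um\n", sep = "")
  invisible(x)
}

#' @export
dim.elemental_map <- function(x) dim(x$values)

#' Detect scan orientation from line positions
#'
#' Lines sharing one X position while spanning Y are vertical; lines sharing
#' one Y position while spanning X are horizontal. Absent or empty positions
#' default to horizontal (positions are then generated from the acquisition
#' parameters). Coordinates are compared with an absolute tolerance since
#' stage readouts are reported well above nanometre precision.
#'
#' @param positions data frame from [parse_positions()], or `NULL`.
#' @param tol absolute coordinate tolerance in micrometres.
#' @return `"horizontal"` or `"vertical"`.
#' @export
detect_orientation <- function(positions, tol = 0.001) {
  if (is.null(positions) || nrow(positions) == 0L) return("horizontal")
  dx <- abs(positions$x_end - positions$x_start)
  dy <- abs(positions$y_end - positions$y_start)
  x_flat <- all(dx <= tol)
  y_flat <- all(dy <= tol)
  if (x_flat && !y_flat) return("vertical")
  if (y_flat && !x_flat) return("horizontal")
  if (x_flat && y_flat) return("horizontal")  # degenerate points: default
  stop("lines extend along both axes beyond tolerance (", tol,
       " um); cannot classify scan as horizontal or vertical", call. = FALSE)
}

#' Build physical axes for a map
#'
#' Along the scan axis, consecutive points are separated by
#' `ablation_speed * acquisition_time` micrometres; across lines the spacing
#' is `space_interval`. Horizontal scans place the scan axis on X; vertical
#' scans swap the two axes. Coordinates are line/point start offsets
#' beginning at 0.
#'
#' @param params an [acq_params()].
#' @param n_points points per line (>= 1).
#' @param n_lines number of lines (>= 1).
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return list with numeric vectors `x` and `y` (micrometres).
#' @export
build_axes <- function(params, n_points, n_lines,
                       orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  stopifnot(n_points >= 1L, n_lines >= 1L)
  step <- params$ablation_speed * params$acquisition_time
  scan <- (seq_len(n_points) - 1L) * step
  cross <- (seq_len(n_lines) - 1L) * params$space_interval
  if (orientation == "horizontal") list(x = scan, y = cross)
  else list(x = cross, y = scan)
}

#' Assemble per-isotope maps from parsed lines
#'
#' Turns an ordered set of `raw_line`s plus acquisition parameters (and
#' optional stage positions) into one [elemental_map()] per monitored
#' isotope. When positions are given, rows are ordered by their cross-axis
#' start coordinate (ties broken by acquisition order) and lines whose end
#' coordinate precedes their start along the scan axis are sample-reversed
#' (serpentine scans). Without positions, acquisition order is used and the
#' scan is taken as horizontal.
#'
#' Lines of unequal length are truncated to the shortest with a warning
#' naming the affected lines (`ragged = "truncate"`), or rejected
#' (`ragged = "error"`).
#'
#' @param lines list of `raw_line` (see [read_line_files()]).
#' @param params an [acq_params()].
#' @param positions optional data frame from [parse_positions()].
#' @param ragged policy for unequal line lengths.
#' @return an object of class `elemental_dataset`: list with `maps` (named
#'   list of `elemental_map`), `parameters` and `orientation`.
#' @export
assemble_dataset <- function(lines, params, positions = NULL,
                             ragged = c("truncate", "error")) {
  ragged <- match.arg(ragged)
  stopifnot(length(lines) >= 1L, inherits(params, "acq_params"))
  iso_sets <- lapply(lines, function(l) sort(names(l$intensities)))
  if (!all(vapply(iso_sets, identical, logical(1L), iso_sets[[1L]]))) {
    stop("line files monitor different isotope sets", call. = FALSE)
  }
  isotopes <- names(lines[[1L]]$intensities)
  ord_idx <- vapply(lines, `[[`, integer(1L), "order_index")
  lines <- lines[order(ord_idx)]
  ord_idx <- sort(ord_idx)

  have_pos <- !is.null(positions) && nrow(positions) > 0L
  if (have_pos && nrow(positions) != length(lines)) {
    stop("positions file has ", nrow(positions), " records but ",
         length(lines), " line files were found", call. = FALSE)
  }
  orientation <- if (have_pos) detect_orientation(positions) else "horizontal"

  reverse <- rep(FALSE, length(lines))
  if (have_pos) {
    pos <- positions[match(ord_idx, positions$line_index), ]
    if (anyNA(pos$line_index)) {
      # indices don't align with file order numbers: fall back to file order
      pos <- positions
    }
    if (orientation == "horizontal") {
      cross_start <- pos$y_start
      reverse <- pos$x_end < pos$x_start
    } else {
      cross_start <- pos$x_start
      reverse <- pos$y_end < pos$y_start
    }
    row_order <- order(cross_start, ord_idx)
  } else {
    row_order <- order(ord_idx)
  }
  lines <- lines[row_order]
  reverse <- reverse[row_order]

  lens <- vapply(lines, function(l) length(l$times), integer(1L))
  n_points <- min(lens)
  if (any(lens != n_points)) {
    bad <- vapply(lines[lens != n_points], `[[`, character(1L), "source_name")
    if (ragged == "error") {
      stop("line files have unequal lengths: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    warning("truncating to ", n_points, " points; longer lines: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }

  axes <- build_axes(params, n_points, length(lines), orientation)
  maps <- lapply(isotopes, function(iso) {
    rows <- lapply(seq_along(lines), function(i) {
      v <- lines[[i]]$intensities[[iso]][seq_len(n_points)]
      if (reverse[i]) rev(v) else v
    })
    m <- do.call(rbind, rows)          # lines x points
    if (orientation == "vertical") m <- t(m)  # image rows follow y axis
    elemental_map(m, axes$x, axes$y, iso)
  })
  names(maps) <- isotopes
  if (!(params$standard %in% isotopes)) {
    stop("standard isotope ", params$standard,
         " is not monitored in this dataset (",
         paste(isotopes, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(maps = maps, parameters = params, orientation = orientation),
            class = "elemental_dataset")
}

#' @export
print.elemental_dataset <- function(x, ...) {
  d <- dim(x$maps[[1L]])
  cat("<elemental_dataset> ", length(x$maps), " isotopes (",
      paste(names(x$maps), collapse = ", "), "), ", d[1L], " x ", d[2L],
      " cells, ", x$orientation, " scan, standard ",
      x$parameters$standard, "\n", sep = "")
  invisible(x)
}

#' Read and assemble a dataset folder in one call
#'
#' Convenience wrapper: parses line files, `parameters.conf` (unless
#' `params` is supplied) and `positions.txt` (if present), then calls
#' [assemble_dataset()].
#'
#' @param dir dataset directory.
#' @param params optional [acq_params()] overriding `parameters.conf`.
#' @param ragged policy for unequal line lengths (see [assemble_dataset()]).
#' @return an `elemental_dataset`.
#' @export
read_dataset <- function(dir, params = NULL, ragged = "truncate") {
  lines <- read_line_files(dir)
  if (is.null(params)) {
    conf <- file.path(dir, "parameters.conf")
    if (!file.exists(conf)) {
      stop("no parameters.conf in '", dir, "' and no parameters supplied; ",
           "required: standard, ablation.speed, acquisition.time, ",
           "space.interval", call. = FALSE)
    }
    params <- parse_parameters(conf)
  }
  pos_path <- file.path(dir, "positions.txt")
  positions <- if (file.exists(pos_path)) parse_positions(pos_path) else NULL
  assemble_dataset(lines, params, positions, ragged = ragged)
}

#' Normalize a map by the internal standard
#'
#' Element-wise ratio of an analyte map to the standard isotope's map.
#' Cells where the standard intensity is zero have no defined ratio and
#' become missing (`NA`); their count is reported via a message. Missing
#' cells render as the colour-map minimum and export as empty CSV fields.
#'
#' @param map analyte `elemental_map` (not yet normalized).
#' @param standard_map the standard isotope's `elemental_map`, same shape
#'   and axes.
#' @return a normalized `elemental_map` of ratios.
#' @export
normalize_map <- function(map, standard_map) {
  stopifnot(inherits(map, "elemental_map"),
            inherits(standard_map, "elemental_map"))
  if (isTRUE(map$normalized)) {
    stop("map ", map$isotope, " is already normalized", call. = FALSE)
  }
  if (!identical(dim(map$values), dim(standard_map$values)) ||
      !isTRUE(all.equal(map$x_coords, standard_map$x_coords)) ||
      !isTRUE(all.equal(map$y_coords, standard_map$y_coords))) {
    stop("analyte and standard maps differ in shape or axes", call. = FALSE)
  }
  denom <- standard_map$values
  ratio <- map$values / denom
  ratio[denom == 0] <- NA_real_
  n_missing <- sum(is.na(ratio))
  if (n_missing > 0L) {
    message(n_missing, " cell(s) with zero standard intensity set to ",
            "missing in ", map$isotope)
  }
  elemental_map(ratio, map$x_coords, map$y_coords, map$isotope,
                normalized = TRUE, standard = standard_map$isotope)
}

#' Normalize every map of a dataset by its standard
#'
#' @param dataset an `elemental_dataset`.
#' @return the dataset with all maps replaced by ratio maps (the standard's
#'   own map becomes 1 wherever its intensity is positive).
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "elemental_dataset"))
  std <- dataset$maps[[dataset$parameters$standard]]
  if (is.null(std)) {
    stop("standard isotope ", dataset$parameters$standard,
         " not present among maps", call. = FALSE)
  }
  dataset$maps <- lapply(dataset$maps, normalize_map, standard_map = std)
  dataset
}

#' Estimate the per-point acquisition time from ICP-MS settings
#'
#' The per-point integration time is the product of the per-isotope dwell
#' time, the number of sweeps per reading, the number of monitored isotopes
#' and the number of replicate readings. Advisory helper for filling in
#' `parameters.conf` (the result is in milliseconds; `acquisition.time`
#' expects seconds).
#'
#' @param dwell_ms per-isotope dwell (residence) time in milliseconds.
#' @param sweeps sweeps per reading.
#' @param n_isotopes number of monitored isotopes.
#' @param replicates replicate readings per point.
#' @return acquisition time per point, in milliseconds.
#' @examples
#' estimate_acquisition_time(30, 3, 3)  # 270 ms
#' @export
estimate_acquisition_time <- function(dwell_ms, sweeps, n_isotopes,
                                      replicates = 1) {
  args <- c(dwell_ms, sweeps, n_isotopes, replicates)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  dwell_ms * sweeps * n_isotopes * replicates
}
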