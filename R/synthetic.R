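#' Spatial field generators for phantoms
#'
#' Each generator returns a function `f(u, v)` of unit coordinates
#' (`u` along the scan, `v` across lines, both in `[0, 1]`) giving expected
#' counts per second. They compose the ground truth of synthetic datasets.
#'
#' `gen_constant` is a flat field; `gen_gradient` ramps linearly between two
#' values along one axis; `gen_blob` is a Gaussian peak on a baseline;
#' `gen_disc` is a filled circle with distinct inside/outside levels.
#'
#' @param value constant level (counts).
#' @param from,to gradient endpoint levels (counts).
#' @param axis `"scan"` or `"cross"`: gradient direction.
#' @param center length-2 unit coordinates `c(u, v)` of the feature centre.
#' @param sigma Gaussian width in unit coordinates.
#' @param amplitude peak height above baseline (counts).
#' @param baseline background level (counts).
#' @param radius disc radius in unit coordinates.
#' @param inside,outside disc levels (counts).
#' @return a vectorized function `f(u, v)`.
#' @name phantom_generators
NULL

#' @rdname phantom_generators
#' @export
gen_constant <- function(value) {
  force(value)
  function(u, v) rep(value, length(u))
}

#' @rdname phantom_generators
#' @export
gen_gradient <- function(from, to, axis = c("scan", "cross")) {
  axis <- match.arg(axis)
  function(u, v) {
    t <- if (axis == "scan") u else v
    from + (to - from) * t
  }
}

#' @rdname phantom_generators
#' @export
gen_blob <- function(center = c(0.5, 0.5), sigma = 0.15, amplitude = 100,
                     baseline = 0) {
  function(u, v) {
    baseline + amplitude *
      exp(-((u - center[1L])^2 + (v - center[2L])^2) / (2 * sigma^2))
  }
}

#' @rdname phantom_generators
#' @export
gen_disc <- function(center = c(0.5, 0.5), radius = 0.3, inside = 100,
                     outside = 1) {
  function(u, v) {
    ifelse((u - center[1L])^2 + (v - center[2L])^2 <= radius^2,
           inside, outside)
  }
}

#' Phantom specification
#'
#' Defines a synthetic sample: its grid shape, the monitored isotopes with a
#' spatial generator each, the internal standard (whose generator must be
#' strictly positive so normalization is defined everywhere), additive
#' Gaussian counting noise, and a seed for reproducibility.
#'
#' The defaults mirror a typical seed-scale line-scan campaign: 23 ablation
#' lines, isotopes C12 (standard, near-uniform matrix carbon), Cu63 and P31
#' with localized features.
#'
#' @param n_lines,n_points grid shape (lines x points per line).
#' @param isotopes isotope labels (any accepted spelling).
#' @param standard the internal-standard isotope; must be in `isotopes`.
#' @param generators named list (by canonical isotope) of generator
#'   functions; defaults provided for the default isotopes.
#' @param noise_sd standard deviation of additive Gaussian noise (counts,
#'   >= 0); noisy values are clamped at 0.
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_lines = 23L, n_points = 120L,
                         isotopes = c("C12", "Cu63", "P31"),
                         standard = "C12",
                         generators = NULL,
                         noise_sd = 0, seed = 1L) {
  isotopes <- isotope_canonical(isotopes)
  standard <- isotope_canonical(standard)
  if (!standard %in% isotopes) {
    stop("standard ", standard, " must be among the monitored isotopes",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(generators)) {
    generators <- default_generators(isotopes, standard)
  } else {
    names(generators) <- isotope_canonical(names(generators))
    missing <- setdiff(isotopes, names(generators))
    if (length(missing) > 0L) {
      stop("no generator for isotope(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(n_lines = as.integer(n_lines),
                 n_points = as.integer(n_points),
                 isotopes = isotopes, standard = standard,
                 generators = generators, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Standard gets a bright near-uniform matrix signal; analytes get a central
# blob and an off-centre disc so maps are visually distinct.
default_generators <- function(isotopes, standard) {
  gens <- list()
  gens[[standard]] <- gen_gradient(900, 1100, axis = "scan")
  others <- setdiff(isotopes, standard)
  feature <- list(gen_blob(center = c(0.5, 0.5), sigma = 0.18,
                           amplitude = 400, baseline = 10),
                  gen_disc(center = c(0.3, 0.6), radius = 0.2,
                           inside = 250, outside = 5),
                  gen_gradient(5, 300, axis = "cross"))
  for (i in seq_along(others)) {
    gens[[others[i]]] <- feature[[1L + (i - 1L) %% length(feature)]]
  }
  gens
}

#' Generate ground-truth phantom matrices
#'
#' Evaluates each isotope's generator on the phantom grid (rows = lines,
#' columns = points along the scan) and adds clamped Gaussian noise when
#' `noise_sd > 0`. Deterministic for a given seed.
#'
#' @param spec a [phantom_spec()].
#' @return named list of `n_lines x n_points` matrices, one per isotope.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  u <- if (spec$n_points == 1L) 0 else
    (seq_len(spec$n_points) - 1L) / (spec$n_points - 1L)
  v <- if (spec$n_lines == 1L) 0 else
    (seq_len(spec$n_lines) - 1L) / (spec$n_lines - 1L)
  U <- matrix(u, nrow = spec$n_lines, ncol = spec$n_points, byrow = TRUE)
  V <- matrix(v, nrow = spec$n_lines, ncol = spec$n_points)
  set.seed(spec$seed)
  out <- lapply(spec$isotopes, function(iso) {
    m <- matrix(spec$generators[[iso]](as.vector(U), as.vector(V)),
                nrow = spec$n_lines)
    if (spec$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), sd = spec$noise_sd),
                      nrow = nrow(m))
      m <- pmax(m, 0)
    }
    m
  })
  names(out) <- spec$isotopes
  std <- out[[spec$standard]]
  if (spec$noise_sd == 0 && any(std <= 0)) {
    stop("standard generator must be strictly positive everywhere",
         call. = FALSE)
  }
  out
}

#' Write a complete synthetic dataset folder
#'
#' Emits one comma-delimited line file per phantom row (named
#' `"line N.xl"`, header `Time,<iso>,...`, time column `k * acquisition
#' time`), a `parameters.conf` and a `positions.txt` consistent with the
#' requested orientation and spacing — the same three formats the reader
#' accepts, so a noise-free phantom survives the write/parse/assemble
#' round trip exactly.
#'
#' @param truth named list of matrices from [make_phantom()] (rows = lines).
#' @param params an [acq_params()].
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param out_dir dataset directory to create.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(truth, params,
                          orientation = c("horizontal", "vertical"),
                          out_dir) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(params, "acq_params"), length(truth) >= 1L)
  shapes <- lapply(truth, dim)
  if (!all(vapply(shapes, identical, logical(1L), shapes[[1L]]))) {
    stop("truth matrices must share one shape", call. = FALSE)
  }
  n_lines <- shapes[[1L]][1L]
  n_points <- shapes[[1L]][2L]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  isotopes <- isotope_canonical(names(truth))
  times <- (seq_len(n_points) - 1L) * params$acquisition_time
  for (i in seq_len(n_lines)) {
    rows <- vapply(seq_len(n_points), function(j) {
      paste(sprintf("%.17g", c(times[j],
                               vapply(truth, function(m) m[i, j],
                                      numeric(1L)))),
            collapse = ",")
    }, character(1L))
    writeLines(c(paste(c("Time", isotopes), collapse = ","), rows),
               file.path(out_dir, paste0("line ", i, ".xl")))
  }
  writeLines(c(paste0("standard=", params$standard),
               paste0("ablation.speed=", params$ablation_speed),
               paste0("acquisition.time=", params$acquisition_time),
               paste0("space.interval=", params$space_interval)),
             file.path(out_dir, "parameters.conf"))
  scan_len <- (n_points - 1L) * params$ablation_speed * params$acquisition_time
  pos <- vapply(seq_len(n_lines), function(i) {
    cross <- (i - 1L) * params$space_interval
    if (orientation == "horizontal") {
      sprintf("line %d\t%.17g\t%.17g\t%.17g\t%.17g", i, 0, cross,
              scan_len, cross)
    } else {
      sprintf("line %d\t%.17g\t%.17g\t%.17g\t%.17g", i, cross, 0,
              cross, scan_len)
    }
  }, character(1L))
  writeLines(c("name\tx_start\ty_start\tx_end\ty_end", pos),
             file.path(out_dir, "positions.txt"))
  invisible(out_dir)
}

#' Generate and write a synthetic dataset in one call
#'
#' @param spec a [phantom_spec()].
#' @param params an [acq_params()]; the default carries the package's
#'   reference scan conditions (standard C12, 10 um/s, 0.270 s, 15 um).
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param out_dir dataset directory to create.
#' @return list with `dir`, `truth` (the phantom matrices) and `spec`,
#'   invisibly.
#' @export
simulate_dataset <- function(spec = phantom_spec(),
                             params = acq_params("C12", 10, 0.270, 15),
                             orientation = "horizontal", out_dir) {
  truth <- make_phantom(spec)
  write_dataset(truth, params, orientation, out_dir)
  invisible(list(dir = out_dir, truth = truth, spec = spec))
}
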