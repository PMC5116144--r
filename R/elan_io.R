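#' Extract the acquisition order from a line-file name
#'
#' Each line file must carry a number giving the order in which the line was
#' ablated, e.g. `"line 1.xl"` ... `"line 10.xl"`. The LAST run of digits in
#' the base name (extension removed) is used, so dataset prefixes such as
#' `"sample7_line 3.xl"` still yield 3.
#'
#' @param name file name or path.
#' @return integer order index.
#' @examples
#' extract_order("line 10.xl")        # 10
#' extract_order("sample7_line 3.xl") # 3
#' @export
extract_order <- function(name) {
  base <- sub("\\.[^.]*$", "", basename(name))
  runs <- regmatches(base, gregexpr("[0-9]+", base))[[1L]]
  if (length(runs) == 0L) {
    stop("file name contains no digits to order by: '", name, "'",
         call. = FALSE)
  }
  as.integer(runs[length(runs)])
}

# Locate the header row (first row whose first field is a time-like header)
# and pick the delimiter among tab/comma/semicolon by majority vote on it.
detect_header <- function(lines) {
  cands <- c(tab = "\t", comma = ",", semicolon = ";")
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    counts <- vapply(cands, function(d) {
      lengths(regmatches(ln, gregexpr(d, ln, fixed = TRUE)))
    }, integer(1L))
    delim <- cands[[which.max(counts)]]
    if (max(counts) == 0L) next
    first <- trimws(gsub('"', "", strsplit(ln, delim, fixed = TRUE)[[1L]][1L]))
    if (grepl("^time", first, ignore.case = TRUE)) {
      return(list(row = i, delim = delim))
    }
  }
  stop("no header row naming a time column found", call. = FALSE)
}

#' Parse one LA-ICP-MS line-scan file
#'
#' Reads a delimited text file holding one ablation line: a header naming the
#' time column and one column per monitored isotope, followed by numeric rows
#' (one per acquired point). The delimiter is auto-detected among tab, comma
#' and semicolon; banner lines before the header are skipped. Negative
#' intensities (detector artifacts) are clamped to zero with a warning.
#'
#' @param path path to the line file.
#' @return an object of class `raw_line`: a list with `source_name`,
#'   `order_index` (from [extract_order()]), `times` (seconds, strictly
#'   increasing) and `intensities` (named list of numeric vectors keyed by
#'   canonical isotope label).
#' @export
parse_line_file <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read line file: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("line file '", path, "' has no data rows", call. = FALSE)
  }
  hdr <- detect_header(lines)
  fields <- function(ln) trimws(gsub('"', "", strsplit(ln, hdr$delim, fixed = TRUE)[[1L]]))
  header <- fields(lines[[hdr$row]])
  if (length(header) < 2L) {
    stop("line file '", path, "' has no isotope columns", call. = FALSE)
  }
  isotopes <- tryCatch(isotope_canonical(header[-1L]), error = function(e) {
    stop("cannot parse isotope column header in '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  body <- lines[-seq_len(hdr$row)]
  if (length(body) == 0L) {
    stop("line file '", path, "' has no data rows", call. = FALSE)
  }
  rows <- lapply(seq_along(body), function(i) {
    f <- fields(body[[i]])
    if (length(f) != length(header)) {
      stop("ragged row ", i, " in '", path, "': expected ", length(header),
           " fields, found ", length(f), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      stop("non-numeric value in data row ", i, " of '", path, "'",
           call. = FALSE)
    }
    v
  })
  mat <- do.call(rbind, rows)
  times <- mat[, 1L]
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("time column in '", path, "' is not strictly increasing",
         call. = FALSE)
  }
  intens <- lapply(seq_along(isotopes), function(j) mat[, j + 1L])
  names(intens) <- isotopes
  n_neg <- sum(vapply(intens, function(v) sum(v < 0), numeric(1L)))
  if (n_neg > 0) {
    warning(n_neg, " negative intensity value(s) in '", basename(path),
            "' clamped to 0", call. = FALSE)
    intens <- lapply(intens, function(v) pmax(v, 0))
  }
  structure(list(source_name = basename(path),
                 order_index = extract_order(path),
                 times = times,
                 intensities = intens),
            class = "raw_line")
}

#' @export
print.raw_line <- function(x, ...) {
  cat("<raw_line> ", x$source_name, " (order ", x$order_index, "): ",
      length(x$times), " points, isotopes ",
      paste(names(x$intensities), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read all line files of a dataset folder
#'
#' Finds every `*.xl` file in `dir`, parses each with [parse_line_file()] and
#' returns them sorted by acquisition order, so the result is independent of
#' directory listing order. All lines must monitor the same isotope set.
#'
#' @param dir dataset directory.
#' @param pattern file-name pattern for line files (default `"\\.xl$"`).
#' @return list of `raw_line`, ordered by `order_index`.
#' @export
read_line_files <- function(dir, pattern = "\\.xl$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) {
    stop("no line files matching '", pattern, "' in '", dir, "'",
         call. = FALSE)
  }
  lines <- lapply(files, parse_line_file)
  ord <- order(vapply(lines, `[[`, integer(1L), "order_index"))
  lines <- lines[ord]
  iso_sets <- lapply(lines, function(l) sort(names(l$intensities)))
  if (!all(vapply(iso_sets, identical, logical(1L), iso_sets[[1L]]))) {
    stop("line files monitor different isotope sets; all lines must share ",
         "the same isotopes", call. = FALSE)
  }
  lines
}

#' Acquisition parameters of a scan
#'
#' The four parameters that define map geometry and normalization: the
#' internal-standard isotope, the laser ablation speed, the per-point
#' acquisition time and the spacing between line centres. An acquisition time
#' above 1.0 s degrades along-scan resolution, so it triggers a warning
#' (not an error).
#'
#' @param standard internal-standard isotope (any accepted spelling).
#' @param ablation_speed laser speed in micrometres per second (> 0).
#' @param acquisition_time per-point acquisition time in seconds (> 0).
#' @param space_interval centre-to-centre line spacing in micrometres (> 0).
#' @return an object of class `acq_params`.
#' @export
acq_params <- function(standard, ablation_speed, acquisition_time,
                       space_interval) {
  standard <- isotope_canonical(standard)
  for (nm in c("ablation_speed", "acquisition_time", "space_interval")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  if (acquisition_time > 1.0) {
    warning("acquisition time ", acquisition_time, " s exceeds 1.0 s; ",
            "elemental distribution information may be lost", call. = FALSE)
  }
  structure(list(standard = standard,
                 ablation_speed = as.numeric(ablation_speed),
                 acquisition_time = as.numeric(acquisition_time),
                 space_interval = as.numeric(space_interval)),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params> standard ", x$standard,
      ", speed ", x$ablation_speed, " um/s",
      ", time ", x$acquisition_time, " s",
      ", interval ", x$space_interval, " um\n", sep = "")
  invisible(x)
}

#' Parse a parameters.conf file
#'
#' Key-value text with keys `standard`, `ablation.speed`, `acquisition.time`
#' and `space.interval` (case-insensitive; `_`, `.` or space between the
#' words; `=` or `:` separators; `#` comments).
#'
#' @param path path to the configuration file.
#' @return an `acq_params` object (see [acq_params()]).
#' @export
parse_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read parameters file: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^=:]+?)\\s*[=:]\\s*(.*?)\\s*$", ln))[[1L]]
    if (length(m) == 0L) next
    key <- tolower(gsub("[ _]", ".", trimws(m[2L])))
    kv[[key]] <- m[3L]
  }
  need <- function(key) {
    if (is.null(kv[[key]])) {
      stop("parameters file '", path, "' is missing key '", key, "'",
           call. = FALSE)
    }
    kv[[key]]
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(need(key)))
    if (is.na(v)) {
      stop("value of '", key, "' in '", path, "' is not numeric",
           call. = FALSE)
    }
    v
  }
  acq_params(standard = need("standard"),
             ablation_speed = num("ablation.speed"),
             acquisition_time = num("acquisition.time"),
             space_interval = num("space.interval"))
}

#' Parse a positions.txt file
#'
#' One whitespace-separated record per line file:
#' `name x_start y_start x_end y_end` (stage coordinates in micrometres).
#' A header line is optional. An empty file yields a zero-row data frame,
#' which callers treat as "positions absent".
#'
#' @param path path to the positions file.
#' @return data frame with columns `line_index`, `x_start`, `y_start`,
#'   `x_end`, `y_end`, in file order.
#' @export
parse_positions <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read positions file: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(line_index = integer(0), x_start = numeric(0),
                      y_start = numeric(0), x_end = numeric(0),
                      y_end = numeric(0))
  if (length(lines) == 0L) return(empty)
  parse_rec <- function(ln) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(f) < 5L) return(NULL)
    coords <- suppressWarnings(as.numeric(f[(length(f) - 3L):length(f)]))
    if (anyNA(coords)) return(NULL)
    name <- paste(f[seq_len(length(f) - 4L)], collapse = " ")
    list(name = name, coords = coords)
  }
  # optional header: drop the first line if its coordinates don't parse
  first <- parse_rec(lines[[1L]])
  recs <- lines
  offset <- 0L
  if (is.null(first)) {
    recs <- lines[-1L]
    offset <- 1L
    if (length(recs) == 0L) return(empty)
  }
  out <- lapply(seq_along(recs), function(i) {
    r <- parse_rec(recs[[i]])
    if (is.null(r)) {
      stop("malformed positions record ", i + offset, " in '", path,
           "': expected 'name x_start y_start x_end y_end'", call. = FALSE)
    }
    idx <- tryCatch(extract_order(r$name), error = function(e) i)
    c(idx, r$coords)
  })
  m <- do.call(rbind, out)
  data.frame(line_index = as.integer(m[, 1L]), x_start = m[, 2L],
             y_start = m[, 3L], x_end = m[, 4L], y_end = m[, 5L])
}

#' CSV dialect definition
#'
#' Predefined dialects for spreadsheet interchange, or a custom one. The
#' field and decimal separators must differ.
#'
#' @param name `"excel"` (comma fields, `.` decimals, CRLF),
#'   `"libreoffice"` (comma fields, `.` decimals, LF) or `"custom"`.
#' @param field_sep,decimal_sep,eol separator characters, used (and required
#'   to be consistent) when `name = "custom"`; override the preset otherwise.
#' @return an object of class `csv_dialect`.
#' @export
csv_dialect <- function(name = c("excel", "libreoffice", "custom"),
                        field_sep = NULL, decimal_sep = NULL, eol = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    excel = list(field_sep = ",", decimal_sep = ".", eol = "\r\n"),
    libreoffice = list(field_sep = ",", decimal_sep = ".", eol = "\n"),
    custom = list(field_sep = ";", decimal_sep = ",", eol = "\n"))
  d <- list(name = name,
            field_sep = if (is.null(field_sep)) preset$field_sep else field_sep,
            decimal_sep = if (is.null(decimal_sep)) preset$decimal_sep else decimal_sep,
            eol = if (is.null(eol)) preset$eol else eol)
  if (identical(d$field_sep, d$decimal_sep)) {
    stop("field and decimal separators must differ", call. = FALSE)
  }
  structure(d, class = "csv_dialect")
}

format_cells <- function(v, dialect, digits = 15L) {
  out <- ifelse(is.na(v), "", sprintf(paste0("%.", digits, "g"), v))
  if (dialect$decimal_sep != ".") {
    out <- gsub(".", dialect$decimal_sep, out, fixed = TRUE)
  }
  out
}

#' Write a matrix (or elemental map) as CSV
#'
#' One numeric row per matrix row, using the dialect's separators. Missing
#' cells are written as empty fields. Values are written with enough digits
#' that re-reading recovers them to at least 12 significant digits
#' (exactly, at the default 17 digits).
#'
#' @param x a numeric matrix or an `elemental_map`.
#' @param path output file path.
#' @param dialect a [csv_dialect()].
#' @param digits significant digits written per value.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(x, path, dialect = csv_dialect("excel"),
                          digits = 17L) {
  if (inherits(x, "elemental_map")) x <- x$values
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(x) == 0L) stop("matrix is empty", call. = FALSE)
  rows <- apply(x, 1L, function(r) {
    paste(format_cells(r, dialect, digits), collapse = dialect$field_sep)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = dialect$eol)
  invisible(path)
}

#' Read back a CSV matrix written by [write_map_csv()]
#'
#' @inheritParams write_map_csv
#' @return numeric matrix; empty fields become `NA`.
#' @export
read_map_csv <- function(path, dialect = csv_dialect("excel")) {
  raw <- readChar(path, file.size(path), useBytes = TRUE)
  rows <- strsplit(raw, "\r\n|\n|\r")[[1L]]
  rows <- rows[nzchar(rows) | seq_along(rows) < length(rows)]
  rows <- rows[nzchar(rows)]
  cells <- strsplit(rows, dialect$field_sep, fixed = TRUE)
  ncol <- lengths(strsplit(paste0(rows, "x"), dialect$field_sep, fixed = TRUE))
  vals <- lapply(seq_along(rows), function(i) {
    f <- cells[[i]]
    f <- c(f, rep("", ncol[i] - length(f)))
    if (dialect$decimal_sep != ".") {
      f <- gsub(dialect$decimal_sep, ".", f, fixed = TRUE)
    }
    ifelse(f == "", NA_real_, suppressWarnings(as.numeric(f)))
  })
  do.call(rbind, vals)
}

SESSION_FORMAT_VERSION <- "1.0"

#' Save an analysis session
#'
#' Writes the dataset's matrices and the render settings to a single archive
#' (a tar container holding one full-precision CSV per isotope and a JSON
#' metadata document), so the analysis can be reloaded later at the same
#' status without re-parsing line files. Conventional extension: `.lai`.
#'
#' @param dataset an `elemental_dataset` (see [assemble_dataset()]).
#' @param settings a list of render/display settings (e.g. a [render_spec()]
#'   or any JSON-representable list); stored verbatim.
#' @param path archive path to create.
#' @return `path`, invisibly.
#' @export
save_session <- function(dataset, settings = list(), path) {
  stopifnot(inherits(dataset, "elemental_dataset"))
  tmp <- tempfile("session")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  isotopes <- names(dataset$maps)
  csv_files <- character(0)
  meta_maps <- list()
  for (iso in isotopes) {
    m <- dataset$maps[[iso]]
    f <- paste0("map_", iso, ".csv")
    write_map_csv(m$values, file.path(tmp, f), csv_dialect("libreoffice"),
                  digits = 17L)
    csv_files <- c(csv_files, f)
    meta_maps[[iso]] <- list(file = f, x_coords = m$x_coords,
                             y_coords = m$y_coords,
                             normalized = isTRUE(m$normalized),
                             standard = m$standard)
  }
  meta <- list(format_version = SESSION_FORMAT_VERSION,
               parameters = unclass(dataset$parameters),
               orientation = dataset$orientation,
               maps = meta_maps,
               settings = settings)
  jsonlite::write_json(meta, file.path(tmp, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  path <- normalizePath(path, mustWork = FALSE)
  old <- setwd(tmp)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(path, files = c("session.json", csv_files), tar = "internal")
  invisible(path)
}

#' Load an analysis session
#'
#' @param path archive written by [save_session()].
#' @return list with elements `dataset` (an `elemental_dataset`) and
#'   `settings` (the list stored at save time).
#' @export
load_session <- function(path) {
  if (!file.exists(path)) {
    stop("session file does not exist: '", path, "'", call. = FALSE)
  }
  tmp <- tempfile("session")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  ok <- tryCatch({
    utils::untar(path, exdir = tmp, tar = "internal")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  meta_path <- file.path(tmp, "session.json")
  if (!ok || !file.exists(meta_path)) {
    stop("'", path, "' is not a readable session archive", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      !identical(as.character(meta$format_version), SESSION_FORMAT_VERSION)) {
    stop("unsupported session format version '", meta$format_version,
         "'; supported versions: ", SESSION_FORMAT_VERSION, call. = FALSE)
  }
  params <- acq_params(meta$parameters$standard,
                       meta$parameters$ablation_speed,
                       meta$parameters$acquisition_time,
                       meta$parameters$space_interval)
  maps <- lapply(names(meta$maps), function(iso) {
    mm <- meta$maps[[iso]]
    vals <- read_map_csv(file.path(tmp, mm$file), csv_dialect("libreoffice"))
    elemental_map(vals, x_coords = as.numeric(mm$x_coords),
                  y_coords = as.numeric(mm$y_coords), isotope = iso,
                  normalized = isTRUE(mm$normalized),
                  standard = if (is.null(mm$standard)) NULL else mm$standard)
  })
  names(maps) <- names(meta$maps)
  dataset <- structure(list(maps = maps, parameters = params,
                            orientation = meta$orientation),
                       class = "elemental_dataset")
  settings <- meta$settings
  list(dataset = dataset, settings = settings)
}
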