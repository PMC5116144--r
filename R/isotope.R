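#' Canonicalize an isotope label
#'
#' Instrument software and publications write the same isotope many ways:
#' `"Cu63"`, `"63Cu"`, `"63Cu+"`, `"^63^Cu^+^"`. This function maps every
#' accepted spelling to the canonical form `"<Symbol><mass>"` (e.g. `"Cu63"`),
#' which is used throughout the package as map names and export file names.
#'
#' @param x character vector of isotope spellings.
#' @return character vector of canonical labels, same length as `x`.
#' @examples
#' isotope_canonical(c("63Cu", "Cu63", "63Cu+", "^63^Cu^+^"))  # all "Cu63"
#' @export
isotope_canonical <- function(x) {
  vapply(as.character(x), function(s) {
    stripped <- gsub("[\\^+[:space:]]", "", s)
    m <- regmatches(stripped, regexec("^([0-9]+)([A-Za-z]{1,2})$", stripped))[[1]]
    if (length(m) == 0L) {
      m <- regmatches(stripped, regexec("^([A-Za-z]{1,2})([0-9]+)$", stripped))[[1]]
      if (length(m) == 0L) {
        stop("cannot parse isotope label: '", s, "'", call. = FALSE)
      }
      sym <- m[2L]; mass <- m[3L]
    } else {
      sym <- m[3L]; mass <- m[2L]
    }
    mass_n <- as.integer(mass)
    if (is.na(mass_n) || mass_n <= 0L) {
      stop("isotope mass number must be a positive integer in '", s, "'",
           call. = FALSE)
    }
    sym <- paste0(toupper(substr(sym, 1L, 1L)),
                  tolower(substring(sym, 2L)))
    paste0(sym, mass_n)
  }, character(1L), USE.NAMES = FALSE)
}

#' Split a canonical isotope label into symbol and mass
#'
#' @param x a canonical label as produced by [isotope_canonical()].
#' @return a list with elements `symbol` (character) and `mass` (integer).
#' @keywords internal
isotope_parts <- function(x) {
  x <- isotope_canonical(x)
  m <- regmatches(x, regexec("^([A-Za-z]{1,2})([0-9]+)$", x))[[1L]]
  list(symbol = m[2L], mass = as.integer(m[3L]))
}
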