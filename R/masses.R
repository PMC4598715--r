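#' @keywords internal
#' Monoisotopic masses of the elements occurring in NRPS/PKS monomer chemistry
#' (CODATA/IUPAC values), plus a few derived constants used throughout.
.ELEMENT_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Cl = 34.96885271,
  Br = 78.9183376
)

#' Mass constants (Da, monoisotopic)
#'
#' `MASS_H2O`, `MASS_NH3`, `MASS_PROTON` and `MASS_H` are the water,
#' ammonia, proton and hydrogen-atom monoisotopic masses used in all
#' condensation, neutral-loss and ionization arithmetic.
#'
#' @name mass-constants
#' @rdname mass-constants
#' @export
MASS_H2O <- 2 * 1.0078250319 + 15.9949146221

#' @rdname mass-constants
#' @export
MASS_NH3 <- 3 * 1.0078250319 + 14.0030740052

#' @rdname mass-constants
#' @export
MASS_PROTON <- 1.00727646688

#' @rdname mass-constants
#' @export
MASS_H <- 1.0078250319

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style formulas such as `"C6H12O4"` or `"C4H8ClNO3"`.
#'
#' @param formula character scalar molecular formula.
#' @return named integer vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  bad <- setdiff(el, names(.ELEMENT_MASS))
  if (length(bad)) stop("unknown element(s) in formula: ", paste(bad, collapse = ", "))
  counts <- tapply(n, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula character vector of molecular formulas.
#' @return numeric vector of monoisotopic masses (Da).
#' @examples
#' formula_mass("C2H5NO2")  # glycine, 75.0320
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    sum(.ELEMENT_MASS[names(counts)] * counts)
  }, numeric(1), USE.NAMES = FALSE)
}
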