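#' Monoisotopic element masses
#'
#' Masses of the most abundant isotope, in dalton, for the elements that occur
#' in polyketide and deoxysugar chemistry (CODATA/AME-derived values, truncated
#' at 1e-6 Da).
#'
#' @return Named numeric vector of monoisotopic masses.
#' @export
element_masses <- function() {
  c(C = 12.000000,
    H = 1.007825,
    N = 14.003074,
    O = 15.994915,
    S = 31.972071,
    P = 30.973762)
}

# mass of a proton, for [M+H]+ adducts
.proton_mass <- 1.007276

#' Create an elemental formula
#'
#' Formulae are named integer vectors over the closed element set of
#' [element_masses()]. Missing elements count as zero; arithmetic is done with
#' [formula_add()].
#'
#' @param ... element counts, e.g. `formula(C = 6, H = 12, O = 6)`.
#' @return Named integer vector of class `pks_formula`.
#' @export
#' @examples
#' chem_formula(C = 6, H = 12, O = 6)
chem_formula <- function(...) {
  x <- c(...)
  if (length(x) == 0) x <- c(C = 0)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all formula components must be named elements")
  bad <- setdiff(names(x), names(element_masses()))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  out <- stats::setNames(integer(length(element_masses())), names(element_masses()))
  agg <- tapply(as.integer(round(x)), names(x), sum)
  out[names(agg)] <- out[names(agg)] + as.integer(agg)
  structure(out, class = "pks_formula")
}

#' Parse a Hill-style formula string
#'
#' @param s formula string such as `"C6H12O6"`.
#' @return A `pks_formula`.
#' @export
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- gsub("\\s", "", s)
  if (s == "" ) return(chem_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(s))
    stop("cannot parse formula string: ", s)
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(n == "", 1L, as.integer(n))
  do.call(chem_formula, as.list(stats::setNames(n, el)))
}

#' Add elemental formulae
#'
#' @param ... `pks_formula` objects (or named vectors coercible to one).
#'   Negative counts express losses (e.g. `-H2O`).
#' @return A `pks_formula`; an error if any net count is negative.
#' @export
formula_add <- function(...) {
  xs <- list(...)
  out <- stats::setNames(integer(length(element_masses())), names(element_masses()))
  for (x in xs) {
    if (is.character(x)) x <- parse_formula(x)
    if (!inherits(x, "pks_formula")) x <- do.call(chem_formula, as.list(x))
    agg <- tapply(as.integer(x), names(x), sum)
    out[names(agg)] <- out[names(agg)] + as.integer(agg)
  }
  if (any(out < 0))
    stop("negative element count after addition: ",
         paste(names(out)[out < 0], collapse = ", "))
  structure(out, class = "pks_formula")
}

# difference without the non-negativity check (for deltas)
formula_delta <- function(x, y) {
  x <- if (is.character(x)) parse_formula(x) else x
  y <- if (is.character(y)) parse_formula(y) else y
  out <- stats::setNames(integer(length(element_masses())), names(element_masses()))
  out[names(x)] <- out[names(x)] + as.integer(x)
  out[names(y)] <- out[names(y)] - as.integer(y)
  structure(out, class = "pks_formula")
}

#' Monoisotopic mass of a formula
#'
#' @param x a `pks_formula`, named vector, or formula string.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")  # 18.0106
monoisotopic_mass <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  masses <- element_masses()
  sum(as.numeric(x[names(masses)]) * masses)
}

#' @export
format.pks_formula <- function(x, ...) {
  # Hill order: C, H, then alphabetical
  ord <- c("C", "H", sort(setdiff(names(x), c("C", "H"))))
  x <- x[ord]
  x <- x[x != 0]
  if (length(x) == 0) return("")
  paste0(names(x), ifelse(x == 1, "", x), collapse = "")
}

#' @export
print.pks_formula <- function(x, ...) {
  cat(format(x), sprintf(" (monoisotopic %.4f Da)\n", monoisotopic_mass(x)), sep = "")
  invisible(x)
}
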