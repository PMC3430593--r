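# IUPAC standard (abridged, 2021) average atomic weights, g/mol.
# Pinned in-source so mass arithmetic is reproducible offline.
.atomic_weights <- c(
  H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990,
  Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, Ar = 39.95, K = 39.098, Ca = 40.078, Sc = 44.956,
  Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Ga = 69.723,
  Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.468, Sr = 87.62, Y = 88.906, Zr = 91.224, Nb = 92.906,
  Mo = 95.95, Ru = 101.07, Rh = 102.906, Pd = 106.42, Ag = 107.868,
  Cd = 112.414, In = 114.818, Sn = 118.710, Sb = 121.760, Te = 127.60,
  I = 126.904, Xe = 131.293, Cs = 132.905, Ba = 137.327, La = 138.905,
  Ce = 140.116, W = 183.84, Pt = 195.084, Au = 196.967, Hg = 200.592,
  Tl = 204.38, Pb = 207.2, Bi = 208.980
)

#' Standard atomic weight of an element
#'
#' @param symbol Element symbol (case-sensitive, e.g. `"Na"`).
#' @return Average atomic weight in g/mol.
#' @examples
#' atomic_weight("C")
#' @export
atomic_weight <- function(symbol) {
  w <- .atomic_weights[symbol]
  if (anyNA(w)) {
    bad <- symbol[is.na(w)]
    stop("unknown element symbol: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(w)
}

#' Parse a molecular formula into element counts
#'
#' Understands simple Hill-style formulas such as `"C3H3NO2"` or `"SO4"`.
#' No parentheses or isotope labels.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C3H3NO2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("malformed formula: ", formula, call. = FALSE)
  elems <- sub("[0-9]+$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]+$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  tapply(counts, elems, sum)[unique(elems)]
}

#' Formula weight from a formula string or count vector
#'
#' @param formula Formula string, or a named numeric vector of element counts.
#' @return Average formula weight in g/mol.
#' @examples
#' formula_mass("H2O")
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(atomic_weight(names(counts)) * as.numeric(counts))
}

# Element counts -> Hill-order formula string (C first, H second, rest
# alphabetical; alphabetical throughout when no carbon).
hill_formula <- function(counts) {
  counts <- counts[counts > 0]
  elems <- names(counts)
  ord <- if ("C" %in% elems) {
    c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  } else sort(elems)
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}
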