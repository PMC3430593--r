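# Theoretical mass arithmetic. Molecules are stored neutral; the substance
# mass re-creates the ionic pairing on paper: salt masses are added and one
# hydrogen mass per unit of balanced counter-ion charge is subtracted
# (cationic counter-ion displaces an acidic proton) or added (anionic
# counter-ion protonates a base). Permanent cations displace nothing.

#' Average molecular mass of a structure
#'
#' Sum of standard atomic weights over all atoms including implicit
#' hydrogens.
#'
#' @param s A [structure_record()].
#' @return Mass in g/mol.
#' @examples
#' \donttest{
#' molecular_mass(parse_structure("N#CCC(=O)O"))  # 85.062
#' }
#' @export
molecular_mass <- function(s) {
  if (s$no_structure)
    stop("No Structure records have no molecular mass", call. = FALSE)
  if (!nrow(s$atoms)) return(0)
  sum(atomic_weight(s$atoms$elem)) +
    sum(hydrogen_counts(s)) * .atomic_weights[["H"]]
}

#' Load and check a salt dictionary
#'
#' Tab-separated columns `id`, `name`, `formula`, `charge`, `mass`. Every
#' entry's stated mass is cross-checked against its formula weight; a
#' discrepancy beyond 1e-3 g/mol aborts the load naming the entry.
#'
#' @param path Dictionary file; defaults to the dictionary shipped with the
#'   package.
#' @return data.frame of validated salt entries.
#' @export
load_salt_dictionary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "salts.tsv", package = "ucdreg")
  if (!file.exists(path) || !nzchar(path))
    stop("salt dictionary not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer", "numeric"))
  if (!nrow(tab)) {
    warning("salt dictionary is empty")
    return(tab)
  }
  need <- c("id", "name", "formula", "charge", "mass")
  if (!all(need %in% names(tab)))
    stop("salt dictionary must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  for (k in seq_len(nrow(tab))) {
    fw <- formula_mass(tab$formula[k])
    if (abs(fw - tab$mass[k]) > 1e-3)
      stop(sprintf(
        "salt '%s': stated mass %.4f differs from formula weight %.4f",
        tab$id[k], tab$mass[k], fw), call. = FALSE)
  }
  if (anyDuplicated(tab$id))
    stop("duplicate salt id in dictionary", call. = FALSE)
  tab
}

#' Substance composition
#'
#' A molecule's counter-ion parts and waters of hydration.
#'
#' @param salts data.frame with columns `id` (salt dictionary id) and
#'   `coeff` (positive stoichiometric coefficient, fractions allowed), or
#'   NULL for a neutral substance.
#' @param hydrate Non-negative integer count of waters of hydration.
#' @return A `ucd_composition` list.
#' @export
substance_composition <- function(salts = NULL, hydrate = 0L) {
  if (is.null(salts))
    salts <- data.frame(id = character(0), coeff = numeric(0),
                        stringsAsFactors = FALSE)
  salts <- as.data.frame(salts, stringsAsFactors = FALSE)
  if (nrow(salts) && any(salts$coeff <= 0))
    stop("stoichiometric coefficients must be positive", call. = FALSE)
  if (hydrate < 0) stop("hydrate count must be non-negative", call. = FALSE)
  structure(list(salts = salts, hydrate = as.integer(hydrate)),
            class = "ucd_composition")
}

# stable text form of a composition; part of substance identity
composition_key <- function(comp) {
  sl <- comp$salts
  part <- if (nrow(sl)) {
    o <- order(sl$id)
    paste(sl$id[o], format(sl$coeff[o], trim = TRUE), sep = "*",
          collapse = "+")
  } else ""
  paste0(part, "~", comp$hydrate, "H2O")
}

#' Theoretical mass of a substance
#'
#' Implements the registration-system mass rule: the neutral molecule mass,
#' plus each salt's formula weight times its stoichiometric coefficient,
#' plus the hydrate waters, minus one hydrogen mass per unit of balanced
#' counter-ion charge (signed: a +1 counter-ion such as sodium displaces an
#' acidic proton, a -1 counter-ion such as chloride arrives as the
#' hydro-acid and contributes a proton). A permanently charged molecule
#' (quaternary ammonium) displaces no protons.
#'
#' @param s Neutral [structure_record()] of the molecule.
#' @param composition A [substance_composition()].
#' @param salt_dict Salt table from [load_salt_dictionary()].
#' @param permanent_cation logical; when NA it is detected from `s`.
#' @return A `ucd_mass_breakdown` list: `molecule`, `salt`, `hydrate`,
#'   `correction` (the signed hydrogen term), `total`, all g/mol.
#' @examples
#' \donttest{
#' s <- standardize(parse_structure("N#CCC(=O)[O-]"))$structure
#' comp <- substance_composition(data.frame(id = "sodium", coeff = 1))
#' substance_mass(s, comp)$total   # 85.062 + 22.990 - 1.008 = 107.044
#' }
#' @export
substance_mass <- function(s, composition = substance_composition(),
                           salt_dict = load_salt_dictionary(),
                           permanent_cation = NA) {
  mol <- molecular_mass(s)
  sl <- composition$salts
  salt_mass <- 0
  net_counter <- 0
  if (nrow(sl)) {
    hit <- match(sl$id, salt_dict$id)
    if (anyNA(hit))
      stop("unknown salt id: ", paste(sl$id[is.na(hit)], collapse = ", "),
           call. = FALSE)
    salt_mass <- sum(sl$coeff * salt_dict$mass[hit])
    net_counter <- sum(sl$coeff * salt_dict$charge[hit])
  }
  if (is.na(permanent_cation)) permanent_cation <- any(is_quaternary_n(s))
  if (permanent_cation && net_counter > 0)
    stop("cationic counter-ion cannot pair with a permanently cationic molecule",
         call. = FALSE)
  n_h <- if (permanent_cation) 0 else net_counter
  hyd <- composition$hydrate * formula_mass("H2O")
  corr <- -n_h * .atomic_weights[["H"]]
  structure(list(molecule = mol, salt = salt_mass, hydrate = hyd,
                 correction = corr, total = mol + salt_mass + hyd + corr),
            class = "ucd_mass_breakdown")
}

#' @export
print.ucd_mass_breakdown <- function(x, ...) {
  cat(sprintf(
    "<substance mass: %.3f = molecule %.3f + salt %.3f + hydrate %.3f %s %.3f H>\n",
    x$total, x$molecule, x$salt, x$hydrate,
    if (x$correction <= 0) "-" else "+", abs(x$correction)))
  invisible(x)
}
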