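# Automatic per-molecule property calculations: formula, molecular weight,
# logP (Open Babel's atomic-contribution model), Lipinski counts, rotatable
# bonds, and the rule-of-five / lead-likeness indicators.

#' Physicochemical property set of a molecule
#'
#' * molecular weight: same arithmetic as [molecular_mass()] (single source
#'   of truth);
#' * logP: Open Babel's atomic-contribution estimate;
#' * H-bond donors / acceptors: classic Lipinski counts (hydrogens on N or
#'   O; number of N plus O atoms);
#' * rotatable bonds: acyclic single bonds between two non-terminal heavy
#'   atoms, triple-bond-adjacent bonds excluded;
#' * `lipinski_pass`: MW <= 500 and logP <= 5 and donors <= 5 and
#'   acceptors <= 10;
#' * `leadlike_pass`: MW <= 350 and logP <= 3.5 and rotatable bonds <= 7.
#'
#' @param s A [structure_record()] (or a structure-bearing molecule row's
#'   molfile parsed into one).
#' @return A `ucd_properties` list.
#' @examples
#' \donttest{
#' compute_properties(parse_structure("N#CCC(=O)O"))
#' }
#' @export
compute_properties <- function(s) {
  if (s$no_structure)
    stop("No Structure molecule: property calculation skipped", call. = FALSE)
  mw <- molecular_mass(s)
  hs <- hydrogen_counts(s)
  donors <- sum(hs[s$atoms$elem %in% c("N", "O")])
  acceptors <- sum(s$atoms$elem %in% c("N", "O"))
  logp <- ob_logp(s)
  rot <- rotatable_bonds(s)
  structure(list(
    formula = structure_formula(s),
    mw = mw, logp = logp, hbd = donors, hba = acceptors,
    rotatable = rot,
    lipinski_pass = mw <= 500 && logp <= 5 && donors <= 5 && acceptors <= 10,
    leadlike_pass = mw <= 350 && logp <= 3.5 && rot <= 7),
    class = "ucd_properties")
}

ob_logp <- function(s) {
  p <- tryCatch(
    ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES",
                                               structure_to_smiles(s),
                                               identity)),
    error = function(e) NULL)
  if (is.null(p) || is.null(p$logP)) NA_real_ else as.numeric(p$logP[1])
}

#' Rotatable bond count
#'
#' Acyclic single bonds between two heavy atoms of degree >= 2, excluding
#' bonds adjacent to a triple bond (their rotation is degenerate).
#'
#' @param s A [structure_record()].
#' @return Integer count.
#' @export
rotatable_bonds <- function(s) {
  if (!nrow(s$bonds)) return(0L)
  deg <- degrees(s)
  rb <- ring_bonds(s)
  bos_triple <- logical(nrow(s$atoms))
  for (k in which(s$bonds$order == 3L)) {
    bos_triple[s$bonds$i[k] + 1L] <- TRUE
    bos_triple[s$bonds$j[k] + 1L] <- TRUE
  }
  n <- 0L
  for (k in seq_len(nrow(s$bonds))) {
    if (s$bonds$order[k] != 1L || rb[k]) next
    i <- s$bonds$i[k]; j <- s$bonds$j[k]
    if (deg[i + 1L] < 2L || deg[j + 1L] < 2L) next
    if (bos_triple[i + 1L] || bos_triple[j + 1L]) next
    n <- n + 1L
  }
  n
}

#' @export
print.ucd_properties <- function(x, ...) {
  cat(sprintf(
    "<%s: MW %.3f, logP %.2f, HBD %d, HBA %d, rot %d, Lipinski %s, lead-like %s>\n",
    x$formula, x$mw, x$logp, x$hbd, x$hba, x$rotatable,
    if (x$lipinski_pass) "pass" else "fail",
    if (x$leadlike_pass) "pass" else "fail"))
  invisible(x)
}
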