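# Canonical uniqueness keys. The registration key has three parts:
#   skeleton | stereo | ratio
# * skeleton: standard InChI of the neutral form with the tetrahedral
#   layers (/t /m /s) removed. InChI's mobile-H canonicalization makes this
#   part tautomer-insensitive; /b (cis/trans) stays, double-bond isomers
#   are different molecules.
# * stereo: per-center geometric parities serialized on InChI canonical
#   atom numbers, bucketed by enhanced stereo group (ABS / AND-n / OR-n)
#   plus explicit "either" (wavy) centers, which SMILES and InChI cannot
#   encode. AND/OR buckets are mirror-canonicalized (a racemate drawn from
#   either enantiomer serializes identically).
# * ratio: the GCD-normalized stereoisomer mixture ratio; mixtures of the
#   same components in different ratios are different molecules.

#' Normalize a stereoisomer mixture ratio
#'
#' Ordered integer ratio divided by its GCD, so 50:50 becomes 1:1 while
#' 30:70 (3:7) stays distinct.
#'
#' @param ratio Integer vector (order matters) or NULL.
#' @return Normalized integer vector, or NULL.
#' @export
normalize_ratio <- function(ratio) {
  if (is.null(ratio) || !length(ratio)) return(NULL)
  ratio <- as.integer(ratio)
  if (any(is.na(ratio) | ratio <= 0L))
    stop("mixture ratio parts must be positive integers", call. = FALSE)
  g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), ratio)
  as.integer(ratio / g)
}

# serialize stereocenters of a standardized structure on InChI canonical
# numbering. ranks: rank[orig 1-based atom] = InChI canonical number.
serialize_stereo <- function(s, ranks) {
  centers <- potential_stereocenters(s)
  eithers <- intersect(either_centers(s), centers)
  grp_of <- rep(NA_character_, nrow(s$atoms))
  for (g in s$stereo_groups) {
    tag <- switch(g$kind, absolute = "ABS",
                  and = paste0("AND", g$ordinal),
                  or = paste0("OR", g$ordinal))
    grp_of[g$atoms + 1L] <- tag
  }
  tok <- list()
  for (ctr in centers) {
    p <- geom_parity(s, ctr, ranks)
    grp <- grp_of[ctr + 1L]
    if (ctr %in% eithers) {
      tok[["EITH"]] <- rbind(tok[["EITH"]],
                             c(ranks[ctr + 1L], "?"))
      next
    }
    if (is.na(p) && is.na(grp)) next      # unannotated center: unspecified
    bucket <- if (is.na(grp)) "ABS" else grp
    sym <- if (is.na(p) || p == 0) "?" else if (p > 0) "+" else "-"
    tok[[bucket]] <- rbind(tok[[bucket]], c(ranks[ctr + 1L], sym))
  }
  if (!length(tok)) return("")
  # canonical bucket naming: relative groups renumbered by smallest member
  is_rel <- grepl("^(AND|OR)", names(tok))
  rel_min <- vapply(tok[is_rel], function(m) min(as.integer(m[, 1])), 0L)
  rel_names <- names(tok)[is_rel]
  new_names <- names(tok)
  kinds <- sub("[0-9]+$", "", rel_names)
  for (kind in unique(kinds)) {
    sel <- rel_names[kinds == kind]
    ord <- sel[order(rel_min[sel])]
    new_names[match(ord, names(tok))] <- paste0(kind, seq_along(ord))
  }
  names(tok) <- new_names
  parts <- vapply(sort(names(tok)), function(nm) {
    m <- tok[[nm]]
    o <- order(as.integer(m[, 1]))
    sym <- m[o, 2]
    # mirror canonicalization for relative (AND/OR) buckets
    if (grepl("^(AND|OR)", nm)) {
      defined <- sym %in% c("+", "-")
      if (any(defined) && sym[which(defined)[1]] == "-") {
        sym[defined] <- ifelse(sym[defined] == "+", "-", "+")
      }
    }
    paste0(nm, "{", paste0(m[o, 1], sym, collapse = ","), "}")
  }, "")
  paste(parts, collapse = ";")
}

#' Canonical keys of a standardized structure
#'
#' Computes the canonical SMILES, standard InChI, and the registration
#' uniqueness key (`ucd_key`). The key is tautomer-insensitive, aware of
#' enhanced stereo groups and "either" centers, independent of input atom
#' ordering, and includes the normalized mixture ratio. `structure_key` is
#' the same key with the ratio stripped — exact structure search uses it so
#' that all ratio variants of one mixture are retrieved together.
#'
#' @param s A standardized, validation-clean [structure_record()].
#' @param mixture_ratio Optional ordered integer ratio of stereoisomer
#'   components (e.g. `c(50, 50)`).
#' @return A `ucd_keys` list: `canonical_smiles`, `inchi`, `ucd_key`,
#'   `structure_key`.
#' @examples
#' \donttest{
#' k1 <- canonical_keys(standardize(parse_structure("O=c1cccc[nH]1"))$structure)
#' k2 <- canonical_keys(standardize(parse_structure("Oc1ccccn1"))$structure)
#' identical(k1$ucd_key, k2$ucd_key)   # tautomers share one key
#' }
#' @export
canonical_keys <- function(s, mixture_ratio = NULL) {
  if (s$no_structure)
    stop("No Structure entries have no chemical key", call. = FALSE)
  check_structure(s)
  res <- structure_to_inchi(s, with_aux = TRUE)
  numbering <- auxinfo_numbering(res$auxinfo)
  n <- nrow(s$atoms)
  ranks <- rep(NA_integer_, n)
  if (length(numbering) == n) {
    ranks[numbering] <- seq_len(n)
  } else {
    # AuxInfo unavailable (rare): fall back to symmetry-class refinement
    # order, still deterministic for a fixed drawing
    ranks <- symmetry_classes(s)
  }
  stereo <- serialize_stereo(s, ranks)
  ratio <- normalize_ratio(mixture_ratio)
  key <- paste0(strip_stereo_layers(res$inchi), "|S:", stereo)
  structure(list(
    canonical_smiles = structure_to_smiles(s),
    inchi = res$inchi,
    structure_key = key,
    ucd_key = paste0(key, "|R:",
                     if (is.null(ratio)) "" else paste(ratio, collapse = ":"))),
    class = "ucd_keys")
}

#' @export
print.ucd_keys <- function(x, ...) {
  cat("<ucd_keys>\n  smiles: ", x$canonical_smiles,
      "\n  inchi:  ", x$inchi, "\n  key:    ", x$ucd_key, "\n", sep = "")
  invisible(x)
}
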