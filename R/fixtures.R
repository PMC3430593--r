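# Deterministic synthetic fixture generator. Produces SDF files with a
# manifest of intended categories and expected dispositions, so the whole
# pipeline (standardize -> validate -> submit -> decide -> search) is
# testable without any external data. Records are built from a fixed
# scaffold list that includes the worked figure compounds (2-cyanoacetic
# acid, the 4-chloropentan-2-ol stereo family, a pyranose sugar).

.clean_scaffolds <- c(
  "N#CCC(=O)O",                    # 2-cyanoacetic acid
  "CC(=O)O", "CCO", "c1ccccc1", "Oc1ccccc1", "Cc1ccccc1",
  "Nc1ccccc1", "c1ccncc1", "C1CCCCC1", "CC(C)O", "CCOCC",
  "CC(=O)Nc1ccccc1", "O=C(O)c1ccccc1", "CCCCO", "CC(=O)C",
  "C[C@@H](O)C[C@H](C)Cl",         # (one stereoisomer of) 4-chloropentan-2-ol
  "OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O",  # glucopyranose
  "CCN", "CCC(=O)O", "OCC(O)CO")

.tautomer_pairs <- list(
  c("O=c1cccc[nH]1", "Oc1ccccn1"),        # 2-pyridone / 2-hydroxypyridine
  c("O=c1cc[nH]cc1", "Oc1ccncc1"),        # 4-pyridone / 4-hydroxypyridine
  c("S=c1cccc[nH]1", "Sc1ccccn1"))        # 2-thiopyridone / 2-mercaptopyridine

# kept disjoint from .clean_scaffolds so collapse groups never overlap
# within one generated file
.acid_scaffolds <- c("CC(C)C(=O)O", "OC(=O)CO", "CCCC(=O)O", "ClCC(=O)O")

# apply a permutation (new order of old 0-based indices) to a record
permute_atoms <- function(s, perm) {
  inv <- integer(length(perm))
  inv[perm + 1L] <- seq_along(perm) - 1L
  out <- s
  out$atoms <- s$atoms[perm + 1L, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$bonds$i <- inv[s$bonds$i + 1L]
  out$bonds$j <- inv[s$bonds$j + 1L]
  out$stereo_groups <- lapply(s$stereo_groups, function(g) {
    g$atoms <- inv[g$atoms + 1L]; g
  })
  out
}

# pentavalent carbon: neopentane plus one bond too many
.valence_error_record <- function() {
  atoms <- data.frame(
    elem = rep("C", 6), charge = 0L, isotope = NA_integer_,
    hcount = NA_integer_,
    x = c(0, 1, 2, 1, 1, 1), y = c(0, 0, 0, 1, -1, 2),
    stringsAsFactors = FALSE)
  bonds <- data.frame(i = c(1L, 1L, 1L, 1L, 1L), j = c(0L, 2L, 3L, 4L, 5L),
                      order = 1L, wedge = "none", stringsAsFactors = FALSE)
  structure_record(atoms, bonds)
}

# norbornane with a wedge on a bridgehead ring bond
.bridge_stereo_record <- function() {
  s <- parse_structure("C1CC2CCC1C2")
  bh <- which(ring_degree(s) >= 3L) - 1L
  k <- which((s$bonds$i %in% bh | s$bonds$j %in% bh))[1]
  if (!(s$bonds$i[k] %in% bh)) {
    tmp <- s$bonds$i[k]; s$bonds$i[k] <- s$bonds$j[k]; s$bonds$j[k] <- tmp
  }
  s$bonds$wedge[k] <- "up"
  s
}

# bend a nitrile out of line (auto-fixable by the geometry rule)
.bent_nitrile_record <- function(smiles = "N#CCC(=O)O") {
  s <- parse_structure(smiles)
  k <- which(s$bonds$order == 3L)[1]
  nitrile_n <- if (s$atoms$elem[s$bonds$i[k] + 1L] == "N")
    s$bonds$i[k] else s$bonds$j[k]
  s$atoms$x[nitrile_n + 1L] <- s$atoms$x[nitrile_n + 1L] + 0.9
  s$atoms$y[nitrile_n + 1L] <- s$atoms$y[nitrile_n + 1L] + 0.9
  s
}

fixture_meta <- function(k) {
  c(PROJECT = "FIXTURE", SCIENTIST = sprintf("gen-%02d", (k %% 5) + 1L),
    NOTEBOOK_REF = sprintf("NB-%04d", k))
}

#' Generate a synthetic fixture SDF with known ground truth
#'
#' Emits an SDF whose records realize the requested categories, together
#' with a manifest stating each record's expected import disposition and a
#' collapse group (records sharing a group must land under one molecule
#' code). Byte-identical output for a given seed.
#'
#' Categories: `clean` (scaffold compounds), `fixable` (drawings the
#' standardizer repairs: bent nitriles, charged acids, doubled wedges),
#' `valence_error` and `stereo_error` (rejected), `duplicate` (atom-order
#' permuted copies of the first clean record), `tautomer` (pairs of
#' tautomeric drawings; count = number of pairs), `salt_variant` (neutral
#' parent plus salt form; count = number of pairs), `no_structure`.
#'
#' @param seed Integer RNG seed.
#' @param counts Named integer vector of per-category record counts.
#' @param path Output SDF path (default: a tempfile).
#' @return list(path, manifest) where manifest is a data.frame with
#'   columns `record`, `category`, `expected`, `group`.
#' @export
generate_fixtures <- function(seed,
                              counts = c(clean = 7, valence_error = 1,
                                         duplicate = 2),
                              path = tempfile(fileext = ".sdf")) {
  all_cats <- c("clean", "fixable", "valence_error", "stereo_error",
                "duplicate", "tautomer", "salt_variant", "no_structure")
  cnt <- stats::setNames(rep(0L, length(all_cats)), all_cats)
  bad <- setdiff(names(counts), all_cats)
  if (length(bad)) stop("unknown fixture categories: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cnt[names(counts)] <- as.integer(counts)
  if (any(cnt < 0L)) stop("counts must be non-negative", call. = FALSE)
  if (sum(cnt) == 0L) stop("all-zero fixture counts", call. = FALSE)
  set.seed(seed)
  recs <- list()
  manifest <- data.frame(record = integer(0), category = character(0),
                         expected = character(0), group = character(0),
                         stringsAsFactors = FALSE)
  grp <- 0L
  push <- function(structure, category, expected, group, extra = character(0)) {
    k <- length(recs) + 1L
    recs[[k]] <<- list(structure = structure,
                       data = c(fixture_meta(k), extra),
                       title = sprintf("%s-%03d", category, k))
    manifest <<- rbind(manifest, data.frame(
      record = k, category = category, expected = expected, group = group,
      stringsAsFactors = FALSE))
  }
  scaff <- sample(.clean_scaffolds)
  clean_structs <- list()
  for (t in seq_len(cnt[["clean"]])) {
    smi <- scaff[((t - 1L) %% length(scaff)) + 1L]
    s <- parse_structure(smi)
    clean_structs[[t]] <- s
    grp <- grp + 1L
    push(s, "clean", "registered", paste0("G", grp))
  }
  # fixable compounds are disjoint from every other category's scaffolds
  # so collapse groups stay distinct within one file
  fix_pool <- list(function() .bent_nitrile_record("N#CCCC"),
                   function() parse_structure("CC(C)(C)C(=O)[O-]"),
                   function() {
                     s <- parse_structure("C[C@@H](O)CC")
                     ctr <- potential_stereocenters(s)[1]
                     k <- which(s$bonds$i == ctr & s$bonds$wedge == "none")[1]
                     s$bonds$wedge[k] <- s$bonds$wedge[
                       which(s$bonds$i == ctr & s$bonds$wedge != "none")[1]]
                     s
                   })
  for (t in seq_len(cnt[["fixable"]])) {
    grp <- grp + 1L
    push(fix_pool[[((t - 1L) %% length(fix_pool)) + 1L]](),
         "fixable", "registered_with_warnings", paste0("G", grp))
  }
  for (t in seq_len(cnt[["valence_error"]])) {
    grp <- grp + 1L
    push(.valence_error_record(), "valence_error", "rejected",
         paste0("G", grp))
  }
  for (t in seq_len(cnt[["stereo_error"]])) {
    grp <- grp + 1L
    push(.bridge_stereo_record(), "stereo_error", "rejected", paste0("G", grp))
  }
  if (cnt[["duplicate"]] > 0L) {
    if (!length(clean_structs))
      stop("duplicate records need at least one clean record", call. = FALSE)
    parent <- clean_structs[[1]]
    parent_grp <- manifest$group[manifest$category == "clean"][1]
    for (t in seq_len(cnt[["duplicate"]])) {
      perm <- sample(nrow(parent$atoms)) - 1L
      push(permute_atoms(parent, perm), "duplicate", "registered", parent_grp)
    }
  }
  for (t in seq_len(cnt[["tautomer"]])) {
    pair <- .tautomer_pairs[[((t - 1L) %% length(.tautomer_pairs)) + 1L]]
    grp <- grp + 1L
    push(parse_structure(pair[1]), "tautomer", "registered", paste0("G", grp))
    push(parse_structure(pair[2]), "tautomer", "registered", paste0("G", grp))
  }
  for (t in seq_len(cnt[["salt_variant"]])) {
    smi <- .acid_scaffolds[((t - 1L) %% length(.acid_scaffolds)) + 1L]
    s <- parse_structure(smi)
    grp <- grp + 1L
    push(s, "salt_variant", "registered", paste0("G", grp))
    push(s, "salt_variant", "registered", paste0("G", grp),
         extra = c(SALT = if (t %% 2L) "sodium" else "potassium",
                   SALT_COEFF = "1"))
  }
  for (t in seq_len(cnt[["no_structure"]])) {
    grp <- grp + 1L
    push(structure_record(no_structure = TRUE), "no_structure", "registered",
         paste0("G", grp), extra = c(NO_STRUCTURE = "TRUE"))
  }
  write_sdf(recs, path)
  list(path = path, manifest = manifest)
}
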