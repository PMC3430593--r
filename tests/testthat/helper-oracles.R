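# Shared fixture builders and independent oracles used across the suite.

meta_ok <- function(extra = list()) {
  c(list(project = "P", scientist = "tester", notebook_ref = "NB-1"), extra)
}

new_registry <- function(users = c(reg1 = "registrar", sub1 = "submitter",
                                   view1 = "viewer")) {
  reg <- ucd_registry()
  for (u in names(users)) add_user(reg, u, users[[u]], team = "T1")
  reg
}

register_one <- function(reg, structure, ...) {
  id <- submit(reg, "reg1", structure, metadata = meta_ok(), ...)
  decide_submission(reg, "reg1", id, "approve")
}

# the six enhanced-stereo drawings of 4-chloropentan-2-ol
stereo_variants <- function() {
  rr <- parse_structure("C[C@@H](O)C[C@H](C)Cl")
  rs <- parse_structure("C[C@@H](O)C[C@@H](C)Cl")
  ctrs <- potential_stereocenters(rr)
  grouped <- function(s, kind) {
    s$stereo_groups <- list(stereo_group(kind, potential_stereocenters(s)))
    s
  }
  wavy <- rr
  k <- which(wavy$bonds$i == ctrs[1] & wavy$bonds$wedge != "none")[1]
  wavy$bonds$wedge[k] <- "either"
  list(abs_rr = rr, abs_rs = rs, and_grp = grouped(rr, "and"),
       or_grp = grouped(rr, "or"), either = wavy,
       unspec = parse_structure("CC(O)CC(C)Cl"))
}

# independent mass oracle: explicit atom-count bookkeeping over the
# pinned weight table, separate from the package's breakdown arithmetic
oracle_substance_mass <- function(s, salts = NULL, hydrate = 0,
                                  dict = load_salt_dictionary(),
                                  permanent_cation = FALSE) {
  counts <- c(table(s$atoms$elem))
  counts <- setNames(as.numeric(counts), names(counts))
  add <- function(counts, formula, times) {
    f <- parse_formula(formula)
    for (e in names(f)) counts[e] <- (counts[e] %||0% 0) + f[[e]] * times
    counts
  }
  `%||0%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
  counts["H"] <- (counts["H"] %||0% 0) + sum(hydrogen_counts(s))
  displaced <- 0
  if (!is.null(salts)) {
    for (k in seq_len(nrow(salts))) {
      row <- dict[match(salts$id[k], dict$id), ]
      counts <- add(counts, row$formula, salts$coeff[k])
      displaced <- displaced + salts$coeff[k] * row$charge
    }
  }
  counts <- add(counts, "H2O", hydrate)
  if (permanent_cation) displaced <- 0
  counts["H"] <- counts["H"] - displaced
  sum(atomic_weight(names(counts)) * counts)
}

# naive subgraph-isomorphism oracle: plain recursive enumeration of
# injective mappings in input order, no candidate ordering, no prescreen
naive_subgraph_match <- function(query, target) {
  nq <- nrow(query$atoms); nt <- nrow(target$atoms)
  if (nq == 0L || nq > nt) return(FALSE)
  qb <- matrix(0L, nq, nq); tb <- matrix(0L, nt, nt)
  for (k in seq_len(nrow(query$bonds))) {
    qb[query$bonds$i[k] + 1, query$bonds$j[k] + 1] <- query$bonds$order[k]
    qb[query$bonds$j[k] + 1, query$bonds$i[k] + 1] <- query$bonds$order[k]
  }
  for (k in seq_len(nrow(target$bonds))) {
    tb[target$bonds$i[k] + 1, target$bonds$j[k] + 1] <- target$bonds$order[k]
    tb[target$bonds$j[k] + 1, target$bonds$i[k] + 1] <- target$bonds$order[k]
  }
  recurse <- function(map) {
    qa <- length(map) + 1L
    if (qa > nq) return(TRUE)
    for (ta in seq_len(nt)) {
      if (ta %in% map) next
      if (query$atoms$elem[qa] != target$atoms$elem[ta]) next
      if (query$atoms$charge[qa] != 0L &&
          query$atoms$charge[qa] != target$atoms$charge[ta]) next
      ok <- TRUE
      for (qprev in seq_len(qa - 1L))
        if (qb[qa, qprev] > 0L &&
            qb[qa, qprev] != tb[ta, map[qprev]]) { ok <- FALSE; break }
      if (ok && recurse(c(map, ta))) return(TRUE)
    }
    FALSE
  }
  recurse(integer(0))
}

shuffle_atoms <- function(s) {
  perm <- sample(nrow(s$atoms)) - 1L
  ucdreg:::permute_atoms(s, perm)
}
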