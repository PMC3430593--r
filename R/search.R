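# Structure search over the registration area: exact (structure-key
# match), substructure (fingerprint prescreen + backtracking subgraph
# isomorphism), similarity (Tanimoto over a hashed path fingerprint).
# Linear scan is deliberate at desk scale; the contract that matters is
# no false negatives from the prescreen.

.fp_bits <- 2048L

# polynomial string hash -> bit position in [1, .fp_bits]
.hash_bit <- function(str) {
  h <- 5381
  for (code in utf8ToInt(str)) h <- (h * 33 + code) %% 2147483647
  as.integer(h %% .fp_bits) + 1L
}

#' Hashed path-based topological fingerprint
#'
#' Enumerates all simple linear paths of 1..`maxlen` atoms (element and
#' bond-order labelled, direction-canonicalized) and hashes each into a
#' fixed-width bit set. Every path of a subgraph is a path of its parent,
#' so a bit set for a substructure query is a subset of any true match's
#' bits: screening by bit containment can never lose a match.
#'
#' @param s A [structure_record()].
#' @param maxlen Maximum path length in atoms.
#' @return Sorted integer vector of set bit positions.
#' @export
path_fingerprint <- function(s, maxlen = 7L) {
  n <- nrow(s$atoms)
  if (!n) return(integer(0))
  adj <- adjacency(s)
  border <- matrix(0L, n, n)
  for (k in seq_len(nrow(s$bonds))) {
    border[s$bonds$i[k] + 1L, s$bonds$j[k] + 1L] <- s$bonds$order[k]
    border[s$bonds$j[k] + 1L, s$bonds$i[k] + 1L] <- s$bonds$order[k]
  }
  # element-only labels: a neutral query atom may match a charged target
  # atom, so charges stay out of the screen (else it could drop true hits)
  label <- s$atoms$elem
  paths <- character(0)
  walk <- function(path) {
    if (length(path) >= 2L) {
      fwd <- label[path]
      for (t in 2:length(path))
        fwd[t] <- paste0(border[path[t - 1L], path[t]], fwd[t])
      fwd <- paste(fwd, collapse = "")
      rev_p <- rev(path)
      bwd <- label[rev_p]
      for (t in 2:length(rev_p))
        bwd[t] <- paste0(border[rev_p[t - 1L], rev_p[t]], bwd[t])
      bwd <- paste(bwd, collapse = "")
      paths <<- c(paths, min(fwd, bwd))
    } else paths <<- c(paths, label[path])
    if (length(path) == maxlen) return()
    for (nb in adj[[path[length(path)]]] + 1L)
      if (!(nb %in% path)) walk(c(path, nb))
  }
  for (a in seq_len(n)) walk(a)
  sort(unique(vapply(unique(paths), .hash_bit, 0L)))
}

#' Tanimoto coefficient of two fingerprints
#'
#' @param a,b Fingerprints as set-bit vectors ([path_fingerprint()]).
#' @return |A intersect B| / |A union B| in [0, 1]; 1 for two empty sets.
#' @export
tanimoto <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# backtracking subgraph-isomorphism matcher (VF2-flavoured: incremental
# mapping with connectivity-consistency pruning). Atom match: element;
# charge only when the query states one. Bond match: equal order.
# Returns TRUE on the first embedding.
subgraph_match <- function(query, target, match_charge_when_set = TRUE) {
  nq <- nrow(query$atoms); nt <- nrow(target$atoms)
  if (nq == 0L || nq > nt) return(FALSE)
  qb <- matrix(0L, nq, nq); tb <- matrix(0L, nt, nt)
  for (k in seq_len(nrow(query$bonds))) {
    qb[query$bonds$i[k] + 1L, query$bonds$j[k] + 1L] <- query$bonds$order[k]
    qb[query$bonds$j[k] + 1L, query$bonds$i[k] + 1L] <- query$bonds$order[k]
  }
  for (k in seq_len(nrow(target$bonds))) {
    tb[target$bonds$i[k] + 1L, target$bonds$j[k] + 1L] <- target$bonds$order[k]
    tb[target$bonds$j[k] + 1L, target$bonds$i[k] + 1L] <- target$bonds$order[k]
  }
  atom_ok <- function(qa, ta) {
    if (query$atoms$elem[qa] != target$atoms$elem[ta]) return(FALSE)
    if (match_charge_when_set && query$atoms$charge[qa] != 0L &&
        query$atoms$charge[qa] != target$atoms$charge[ta]) return(FALSE)
    TRUE
  }
  # order query atoms so each (after the first) touches an earlier one
  ord <- integer(0)
  remaining <- seq_len(nq)
  ord <- remaining[1]; remaining <- remaining[-1]
  while (length(remaining)) {
    nxt <- remaining[vapply(remaining, function(q)
      any(qb[q, ord] > 0L), TRUE)]
    pick <- if (length(nxt)) nxt[1] else remaining[1]
    ord <- c(ord, pick); remaining <- setdiff(remaining, pick)
  }
  mapping <- rep(NA_integer_, nq)
  used <- rep(FALSE, nt)
  try_at <- function(pos) {
    if (pos > nq) return(TRUE)
    qa <- ord[pos]
    qnbs <- which(qb[qa, ] > 0L)
    mapped_nbs <- qnbs[!is.na(mapping[qnbs])]
    cands <- if (length(mapped_nbs)) {
      which(tb[mapping[mapped_nbs[1]], ] > 0L)
    } else seq_len(nt)
    for (ta in cands) {
      if (used[ta] || !atom_ok(qa, ta)) next
      ok <- TRUE
      for (qn in mapped_nbs)
        if (tb[ta, mapping[qn]] != qb[qa, qn]) { ok <- FALSE; break }
      if (!ok) next
      mapping[qa] <<- ta; used[ta] <<- TRUE
      if (try_at(pos + 1L)) return(TRUE)
      mapping[qa] <<- NA_integer_; used[ta] <<- FALSE
    }
    FALSE
  }
  try_at(1L)
}

search_hit <- function(reg, mol_rows, scores = NULL) {
  hits <- lapply(seq_len(nrow(mol_rows)), function(k) {
    code <- mol_rows$code[k]
    subs <- reg$substances[reg$substances$molecule_code == code, , drop = FALSE]
    bats <- reg$batches[reg$batches$substance_code %in% subs$code, ,
                        drop = FALSE]
    structure(list(molecule_code = code,
                   substances = subs$code, batches = bats$code,
                   score = if (is.null(scores)) 1 else scores[k]),
              class = "ucd_search_hit")
  })
  hits
}

#' @export
print.ucd_search_hit <- function(x, ...) {
  cat(sprintf("<hit %s score %.3f: %d substance(s), %d batch(es)>\n",
              x$molecule_code, x$score, length(x$substances),
              length(x$batches)))
  invisible(x)
}

search_pool <- function(reg, include_archived) {
  m <- reg$molecules[!reg$molecules$no_structure, , drop = FALSE]
  if (!include_archived) m <- m[m$status == "active", , drop = FALSE]
  m
}

#' Exact structure search
#'
#' Matches on the structure-only key (mixture ratio stripped), so all
#' ratio variants of one stereoisomer mixture — and any tautomeric drawing
#' of the query — are retrieved together.
#'
#' @param reg A [ucd_registry()].
#' @param query Structure text or [structure_record()].
#' @param include_archived Also search archived molecules.
#' @return List of search hits (molecule code, its substances and batches,
#'   score 1).
#' @export
exact_search <- function(reg, query, include_archived = FALSE) {
  s <- if (inherits(query, "ucd_structure")) query else parse_structure(query)
  if (s$no_structure)
    stop("a No Structure query has nothing to match", call. = FALSE)
  norm <- standardize(s)
  rep <- validate_structure(norm$structure)
  if (!rep$registrable)
    stop("query fails validation and cannot be standardized for search",
         call. = FALSE)
  key <- canonical_keys(norm$structure)$structure_key
  pool <- search_pool(reg, include_archived)
  search_hit(reg, pool[pool$structure_key == key, , drop = FALSE])
}

#' Substructure search
#'
#' Subgraph-isomorphism semantics on element and bond order (and charge
#' where the query specifies one), behind a path-fingerprint prescreen
#' that can only discard guaranteed non-matches.
#'
#' @param reg A [ucd_registry()].
#' @param query Structure text or [structure_record()] used as the pattern.
#' @param include_archived Also search archived molecules.
#' @return List of search hits.
#' @export
substructure_search <- function(reg, query, include_archived = FALSE) {
  s <- if (inherits(query, "ucd_structure")) query else parse_structure(query)
  if (s$no_structure || !nrow(s$atoms))
    stop("empty substructure query", call. = FALSE)
  qfp <- path_fingerprint(s)
  pool <- search_pool(reg, include_archived)
  keep <- logical(nrow(pool))
  for (k in seq_len(nrow(pool))) {
    t <- read_molfile(pool$molfile[k])
    if (length(setdiff(qfp, path_fingerprint(t)))) next  # prescreen
    keep[k] <- subgraph_match(s, t)
  }
  search_hit(reg, pool[keep, , drop = FALSE])
}

#' Similarity search
#'
#' Tanimoto coefficient over the hashed path fingerprint; hits at or above
#' the threshold, sorted by descending score with ties broken by molecule
#' code.
#'
#' @param reg A [ucd_registry()].
#' @param query Structure text or [structure_record()].
#' @param threshold Minimum Tanimoto score in [0, 1].
#' @param include_archived Also search archived molecules.
#' @return List of search hits with scores.
#' @export
similarity_search <- function(reg, query, threshold = 0.7,
                              include_archived = FALSE) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  s <- if (inherits(query, "ucd_structure")) query else parse_structure(query)
  qfp <- path_fingerprint(s)
  pool <- search_pool(reg, include_archived)
  scores <- vapply(seq_len(nrow(pool)), function(k)
    tanimoto(qfp, path_fingerprint(read_molfile(pool$molfile[k]))), 0)
  keep <- which(scores >= threshold)
  keep <- keep[order(-scores[keep], pool$code[keep])]
  search_hit(reg, pool[keep, , drop = FALSE], scores[keep])
}
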