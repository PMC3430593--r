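test_that("exact search retrieves all ratio variants and tautomer drawings", {
  reg <- new_registry()
  v <- stereo_variants()$and_grp
  register_one(reg, v, mixture_ratio = c(50, 50))
  register_one(reg, v, mixture_ratio = c(30, 70))
  expect_equal(nrow(molecules(reg)), 2L)       # one code per ratio
  hits <- exact_search(reg, v)
  expect_length(hits, 2L)

  reg2 <- new_registry()
  register_one(reg2, "O=c1cccc[nH]1")
  hits2 <- exact_search(reg2, "Oc1ccccn1")     # the other tautomer drawing
  expect_length(hits2, 1L)

  expect_length(exact_search(reg2, "CCCCCCCC"), 0L)
  expect_error(exact_search(reg2, structure_record(no_structure = TRUE)),
               "No Structure")
})

test_that("every registered molecule retrieves itself exactly", {
  reg <- new_registry()
  pool <- c("N#CCC(=O)O", "CCO", "c1ccccc1", "CC(=O)Nc1ccccc1",
            "C[C@@H](O)C[C@H](C)Cl", "O=c1cccc[nH]1")
  for (smi in pool) register_one(reg, smi)
  for (k in seq_len(nrow(molecules(reg)))) {
    hits <- exact_search(reg, read_molfile(molecules(reg)$molfile[k]))
    expect_true(molecules(reg)$code[k] %in%
                  vapply(hits, `[[`, "", "molecule_code"))
  }
})

test_that("substructure search agrees with the naive oracle", {
  reg <- new_registry()
  pool <- c("N#CCC(=O)O", "CCO", "c1ccccc1", "Oc1ccccc1", "CC(=O)O",
            "CC(=O)Nc1ccccc1", "C1CCCCC1", "CCN", "O=C(O)c1ccccc1",
            "CCOCC", "CC(C)O", "c1ccncc1", "CCC(=O)O", "NCCO",
            "C[C@@H](O)C[C@H](C)Cl")
  for (smi in pool) register_one(reg, smi)
  queries <- c("C#N", "c1ccccc1", "C=O", "CO", "CCO", "NC=O", "c1ccncc1",
               "CCl", "OCO", "CN")
  m <- molecules(reg)
  for (q in queries) {
    qs <- parse_structure(q)
    got <- sort(vapply(substructure_search(reg, qs), `[[`, "",
                       "molecule_code"))
    want <- m$code[vapply(seq_len(nrow(m)), function(k)
      naive_subgraph_match(qs, read_molfile(m$molfile[k])), TRUE)]
    expect_equal(got, sort(want), info = q)
  }
})

test_that("a full registered structure is its own substructure", {
  reg <- new_registry()
  register_one(reg, "CC(=O)Nc1ccccc1")
  hits <- substructure_search(reg, "CC(=O)Nc1ccccc1")
  expect_length(hits, 1L)
  expect_error(substructure_search(reg, structure_record(no_structure = TRUE)),
               "empty")
})

test_that("similarity scores are exact for self, symmetric, and ranked", {
  reg <- new_registry()
  for (smi in c("N#CCC(=O)O", "CCO", "c1ccccc1")) register_one(reg, smi)
  hits <- similarity_search(reg, "N#CCC(=O)O", threshold = 0.0)
  expect_equal(hits[[1]]$score, 1.0)
  expect_equal(hits[[1]]$molecule_code, "UCD00000001")
  expect_true(all(diff(vapply(hits, `[[`, 0, "score")) <= 0))

  a <- path_fingerprint(parse_structure("CCO"))
  b <- path_fingerprint(parse_structure("CCN"))
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_equal(tanimoto(a, a), 1.0)

  # threshold 1 with no identical molecule registered
  expect_length(similarity_search(reg, "CCCCCCN", threshold = 1.0), 0L)
  # disjoint chemistry scores near zero
  lo <- tanimoto(path_fingerprint(parse_structure("CCCCC")),
                 path_fingerprint(parse_structure("O")))
  expect_lt(lo, 0.05)
  expect_error(similarity_search(reg, "CCO", threshold = 1.5), "0, 1")
})

test_that("archived molecules are excluded unless asked for", {
  reg <- new_registry()
  res <- register_one(reg, "CCO")
  archive_batch(reg, "reg1", res$batch_code)
  expect_length(exact_search(reg, "CCO"), 0L)
  expect_length(exact_search(reg, "CCO", include_archived = TRUE), 1L)
  expect_length(similarity_search(reg, "CCO", 0.9), 0L)
  expect_length(similarity_search(reg, "CCO", 0.9, include_archived = TRUE), 1L)
})

test_that("the fingerprint prescreen never loses a true match", {
  set.seed(5)
  pool <- c("N#CCC(=O)O", "CC(=O)Nc1ccccc1", "O=C(O)c1ccccc1",
            "OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O", "CCOCC")
  for (smi in pool) {
    t <- parse_structure(smi)
    # any connected induced path of the target is a guaranteed substructure
    fp_t <- path_fingerprint(t)
    for (rep in 1:3) {
      start <- sample(nrow(t$atoms), 1) - 1L
      adjs <- ucdreg:::adjacency(t)
      path <- start
      while (length(path) < 4) {
        nxt <- setdiff(adjs[[path[length(path)] + 1L]], path)
        if (!length(nxt)) break
        path <- c(path, nxt[1])
      }
      keep <- sort(path)
      sub <- t
      sel <- which(t$bonds$i %in% keep & t$bonds$j %in% keep &
                     (t$bonds$i %in% path[-1] | t$bonds$j %in% path[-1]))
      # build the path subgraph record
      remap <- match(t$bonds$i, keep) - 1L
      q <- structure_record(
        t$atoms[keep + 1L, ],
        data.frame(i = match(t$bonds$i[sel], keep) - 1L,
                   j = match(t$bonds$j[sel], keep) - 1L,
                   order = t$bonds$order[sel], wedge = "none"))
      expect_length(setdiff(path_fingerprint(q), fp_t), 0L)
      expect_true(ucdreg:::subgraph_match(q, t))
    }
  }
})
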