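test_that("neutralization follows the one-hydrogen-per-charge rule", {
  carbox <- neutralize(parse_structure("N#CCC(=O)[O-]"))
  expect_equal(carbox$proton_delta, 1L)
  expect_equal(net_charge(carbox$structure), 0L)
  expect_equal(structure_to_smiles(carbox$structure),
               structure_to_smiles(parse_structure("N#CCC(=O)O")))

  ammonium <- neutralize(parse_structure("CC[NH3+]"))
  expect_equal(ammonium$proton_delta, -1L)
  expect_equal(structure_to_smiles(ammonium$structure),
               structure_to_smiles(parse_structure("CCN")))

  quat <- neutralize(parse_structure("C[N+](C)(C)C"))
  expect_true(quat$permanent_cation)
  expect_equal(quat$proton_delta, 0L)
  expect_equal(net_charge(quat$structure), 1L)

  neutral <- neutralize(parse_structure("CCO"))
  expect_equal(neutral$proton_delta, 0L)
  expect_length(neutral$applied_rules, 0L)

  zwit <- neutralize(parse_structure("[NH3+]CC(=O)[O-]"))  # glycine zwitterion
  expect_equal(zwit$proton_delta, 0L)
  expect_equal(net_charge(zwit$structure), 0L)
})

test_that("neutralization conserves the heavy-atom multigraph", {
  for (smi in c("N#CCC(=O)[O-]", "CC[NH3+]", "[NH3+]CC(=O)[O-]",
                "C[N+](C)(C)C", "[O-]c1ccccc1")) {
    s <- parse_structure(smi)
    out <- neutralize(s)$structure
    expect_identical(out$atoms$elem, s$atoms$elem, info = smi)
    expect_identical(out$bonds[c("i", "j", "order")],
                     s$bonds[c("i", "j", "order")], info = smi)
  }
})

test_that("an unneutralizable drawn cation is refused", {
  na_plus <- structure_record(
    data.frame(elem = "Na", charge = 1L, isotope = NA_integer_,
               hcount = NA_integer_, x = 0, y = 0))
  expect_error(neutralize(na_plus), "cannot be neutralized")
})

test_that("bent triple bonds are straightened to 180 degrees", {
  bent <- ucdreg:::.bent_nitrile_record()
  out <- standardize(bent)
  expect_true("linear_triple_bond" %in% out$applied_rules)
  s <- out$structure
  k <- which(s$bonds$order == 3L)
  b <- s$bonds$i[k]; c2 <- s$bonds$j[k]
  other <- setdiff(unlist(ucdreg:::adjacency(s)[[b + 1L]]), c2)
  if (!length(other)) { tmp <- b; b <- c2; c2 <- tmp
                        other <- setdiff(unlist(ucdreg:::adjacency(s)[[b + 1L]]), c2) }
  ang <- ucdreg:::angle_deg(s$atoms$x[c2 + 1], s$atoms$y[c2 + 1],
                            s$atoms$x[b + 1], s$atoms$y[b + 1],
                            s$atoms$x[other[1] + 1], s$atoms$y[other[1] + 1])
  expect_gt(ang, 178)
})

test_that("redundant and misdirected wedges are repaired", {
  s <- parse_structure("C[C@@H](O)CC")
  ctr <- potential_stereocenters(s)[1]
  w <- which(s$bonds$i == ctr & s$bonds$wedge != "none")[1]
  dir <- s$bonds$wedge[w]
  extra <- which(s$bonds$i == ctr & s$bonds$wedge == "none")[1]
  s$bonds$wedge[extra] <- dir
  out <- standardize(s)
  expect_true("redundant_wedges" %in% out$applied_rules)
  expect_equal(sum(out$structure$bonds$i == ctr &
                     out$structure$bonds$wedge == dir), 1L)

  s2 <- parse_structure("C[C@@H](O)CC")
  w2 <- which(s2$bonds$i == ctr & s2$bonds$wedge != "none")[1]
  tmp <- s2$bonds$i[w2]; s2$bonds$i[w2] <- s2$bonds$j[w2]; s2$bonds$j[w2] <- tmp
  out2 <- standardize(s2)
  expect_true("wedge_to_stereocenter" %in% out2$applied_rules)
  expect_true(all(out2$structure$bonds$i[
    out2$structure$bonds$wedge %in% c("up", "down")] == ctr))
})

test_that("standardization is idempotent across diverse inputs", {
  pool <- c("N#CCC(=O)[O-]", "CC[NH3+]", "C[N+](C)(C)C", "CCO",
            "C[C@@H](O)C[C@H](C)Cl", "c1ccccc1O",
            "OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O")
  for (smi in pool) {
    once <- standardize(parse_structure(smi))
    twice <- standardize(once$structure)
    expect_length(twice$applied_rules, 0L)
    expect_true(ucdreg:::same_structure(twice$structure, once$structure),
                info = smi)
  }
  bent <- standardize(ucdreg:::.bent_nitrile_record())
  again <- standardize(bent$structure)
  expect_length(again$applied_rules, 0L)
})

test_that("the validator detects the unfixable drawing errors", {
  expect_equal(validate_structure(ucdreg:::.valence_error_record())$errors$rule,
               "valence")
  expect_true("bridge_stereo" %in%
                validate_structure(ucdreg:::.bridge_stereo_record())$errors$rule)

  clean <- standardize(parse_structure("N#CCC(=O)O"))$structure
  rep <- validate_structure(clean)
  expect_equal(nrow(rep$errors), 0L)
  expect_true(rep$registrable)

  # wedge touching no stereocenter at all
  s <- parse_structure("CCO")
  s$bonds$wedge[1] <- "up"
  expect_true("ambiguous_stereo" %in% validate_structure(s)$errors$rule)

  # unmarked stereocenter is a warning, not an error
  un <- parse_structure("CC(N)O")
  rep2 <- validate_structure(un)
  expect_true(rep2$registrable)
  expect_true("unmarked_stereocenter" %in% rep2$warnings$rule)
})

test_that("No Structure records pass standardization and validation untouched", {
  ns <- structure_record(no_structure = TRUE)
  out <- standardize(ns)
  expect_length(out$applied_rules, 0L)
  expect_true(validate_structure(ns)$registrable)
})
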