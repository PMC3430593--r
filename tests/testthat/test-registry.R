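test_that("first approval mints the exemplar code shapes", {
  reg <- new_registry()
  res <- register_one(reg, "N#CCC(=O)O")
  expect_equal(res$molecule_code, "UCD00000001")
  expect_equal(res$substance_code, "UCD00000001-A")
  expect_equal(res$batch_code, 1L)
})

test_that("a charged drawing is stored normalized and salts make new letters", {
  reg <- new_registry()
  id <- submit(reg, "sub1", "N#CCC(=O)[O-]",
               substance_composition(data.frame(id = "sodium", coeff = 1)),
               metadata = meta_ok())
  sub_row <- submissions(reg)[1, ]
  expect_equal(sub_row$rules, "neutralize")
  expect_equal(net_charge(read_molfile(sub_row$molfile)), 0L)
  r1 <- decide_submission(reg, "reg1", id, "approve")

  # same acid as the free acid, then as the potassium salt
  r2 <- register_one(reg, "N#CCC(=O)O")
  r3 <- register_one(reg, "OC(=O)CC#N",
                     composition = substance_composition(
                       data.frame(id = "potassium", coeff = 1)))
  expect_equal(r2$molecule_code, r1$molecule_code)
  expect_equal(r3$molecule_code, r1$molecule_code)
  expect_setequal(substances(reg)$letter, c("A", "B", "C"))
  expect_equal(nrow(molecules(reg)), 1L)
  expect_equal(nrow(batches(reg)), 3L)
})

test_that("substance identity includes hydrate count and stoichiometry", {
  reg <- new_registry()
  r1 <- register_one(reg, "CC(=O)O")
  r2 <- register_one(reg, "CC(=O)O",
                     composition = substance_composition(hydrate = 1L))
  r3 <- register_one(reg, "CC(=O)O",
                     composition = substance_composition(
                       data.frame(id = "sodium", coeff = 0.5)))
  expect_equal(length(unique(c(r1$substance_code, r2$substance_code,
                               r3$substance_code))), 3L)
  expect_equal(nrow(molecules(reg)), 1L)
})

test_that("the permission matrix is exactly viewer/submitter/registrar", {
  reg <- new_registry()
  expect_error(submit(reg, "view1", "CCO", metadata = meta_ok()),
               "lacks the 'submitter'")
  id <- submit(reg, "sub1", "CCO", metadata = meta_ok())
  expect_error(decide_submission(reg, "sub1", id, "approve"),
               "lacks the 'registrar'")
  res <- decide_submission(reg, "reg1", id, "approve")
  expect_error(reassign_batch(reg, "sub1", res$batch_code, "CCC"),
               "lacks the 'registrar'")
  expect_error(archive_batch(reg, "sub1", res$batch_code),
               "lacks the 'registrar'")
  expect_error(submit(reg, "ghost", "CCO", metadata = meta_ok()),
               "unknown user")
})

test_that("submission gatekeeping: metadata, numbers, normalization approval", {
  reg <- new_registry()
  expect_error(submit(reg, "sub1", "CCO",
                      metadata = list(project = "P", scientist = "s")),
               "notebook_ref")
  expect_error(submit(reg, "sub1", "CCO",
                      metadata = meta_ok(list(experimental_mw = "heavy"))),
               "only numbers")
  ok <- submit(reg, "sub1", "CCO",
               metadata = meta_ok(list(experimental_mw = "46.07")))
  expect_true(ok >= 1L)
  expect_error(submit(reg, "sub1", "CCO", metadata = meta_ok(),
                      approve_normalization = FALSE),
               "approval of the normalized")
  expect_error(submit(reg, "sub1", ucdreg:::.valence_error_record(),
                      metadata = meta_ok()),
               "validation errors")
})

test_that("rejected submissions stay, and resubmission gets a fresh id", {
  reg <- new_registry()
  id1 <- submit(reg, "sub1", "CCO", metadata = meta_ok())
  decide_submission(reg, "reg1", id1, "reject", reason = "wrong notebook")
  expect_equal(submissions(reg)$state[1], "rejected")
  expect_equal(submissions(reg)$reason[1], "wrong notebook")
  expect_error(decide_submission(reg, "reg1", id1, "approve"),
               "not awaiting decision")
  id2 <- submit(reg, "sub1", "CCO", metadata = meta_ok())
  expect_gt(id2, id1)
  expect_equal(nrow(molecules(reg)), 0L)  # nothing reached registration
})

test_that("uniqueness holds under permuted, salted and tautomeric resubmission", {
  reg <- new_registry()
  set.seed(3)
  base <- standardize(parse_structure("N#CCC(=O)O"))$structure
  register_one(reg, base)
  register_one(reg, shuffle_atoms(base))
  register_one(reg, shuffle_atoms(base),
               composition = substance_composition(
                 data.frame(id = "sodium", coeff = 1)))
  expect_equal(nrow(molecules(reg)), 1L)
  reg2 <- new_registry()
  register_one(reg2, "O=c1cccc[nH]1")
  register_one(reg2, "Oc1ccccn1")
  expect_equal(nrow(molecules(reg2)), 1L)
  expect_equal(nrow(batches(reg2)), 2L)
})

test_that("reassignment cascades archive emptied parents and keeps rows", {
  reg <- new_registry()
  rx <- register_one(reg, "CCO")
  ry <- register_one(reg, "CCC")
  # sole batch of molecule X moved to molecule Y
  out <- reassign_batch(reg, "reg1", rx$batch_code, "CCC")
  expect_equal(out$molecule_code, ry$molecule_code)
  mX <- molecules(reg)[molecules(reg)$code == rx$molecule_code, ]
  expect_equal(mX$status, "archived")
  expect_equal(substances(reg)$status[substances(reg)$molecule_code ==
                                        rx$molecule_code], "archived")
  expect_equal(nrow(batches(reg, include_archived = TRUE)), 2L)

  # one of two batches moved: no cascade
  reg2 <- new_registry()
  a1 <- register_one(reg2, "CCO")
  register_one(reg2, "CCO")
  register_one(reg2, "CCC")
  reassign_batch(reg2, "reg1", a1$batch_code, "CCC")
  expect_equal(molecules(reg2)$status[molecules(reg2)$code ==
                                        a1$molecule_code], "active")

  expect_error(reassign_batch(reg, "reg1", 999L, "CCC"), "no such batch")
})

test_that("a No Structure batch can be re-homed once elucidated", {
  reg <- new_registry()
  id <- submit(reg, "sub1", no_structure = TRUE, metadata = meta_ok())
  res <- decide_submission(reg, "reg1", id, "approve")
  expect_true(molecules(reg)$no_structure[1])
  out <- reassign_batch(reg, "reg1", res$batch_code, "N#CCC(=O)O",
                        reason = "structure elucidated by NMR")
  expect_false(molecules(reg)[molecules(reg)$code == out$molecule_code,
                              "no_structure"])
  ev <- audit_log(reg)
  moved <- ev[ev$action == "batch_reassigned", ]
  expect_equal(nrow(moved), 1L)
  expect_false(moved$prior == moved$new)
})

test_that("No Structure submissions never merge", {
  reg <- new_registry()
  for (t in 1:3)
    decide_submission(reg, "reg1",
                      submit(reg, "sub1", no_structure = TRUE,
                             metadata = meta_ok()), "approve")
  expect_equal(nrow(molecules(reg)), 3L)
})

test_that("archiving the last batch cascades and reactivation works", {
  reg <- new_registry()
  res <- register_one(reg, "CCO")
  archive_batch(reg, "reg1", res$batch_code, reason = "withdrawn")
  expect_equal(batches(reg, include_archived = TRUE)$status, "archived")
  expect_equal(molecules(reg)$status, "archived")
  expect_error(archive_batch(reg, "reg1", res$batch_code), "already")
  # approving the same chemistry again reactivates the archived molecule
  res2 <- register_one(reg, "CCO")
  expect_equal(res2$molecule_code, res$molecule_code)
  expect_equal(molecules(reg)$status, "active")
  expect_true("molecule_reactivated" %in% audit_log(reg)$action)
})

test_that("restricted fields are visible to the owning team only", {
  reg <- ucd_registry()
  add_user(reg, "alice", "submitter", team = "pharmacology")
  add_user(reg, "bob", "viewer", team = "chemistry")
  add_user(reg, "root", "registrar", team = "chemistry")
  id <- submit(reg, "alice", "CCO", metadata = meta_ok(),
               restricted = list(study_activity = list(team = "pharmacology",
                                                       value = "EC50 2uM")))
  decide_submission(reg, "root", id, "approve")
  expect_equal(enforce_access(reg, "alice", id, "study_activity"), "EC50 2uM")
  expect_equal(enforce_access(reg, "bob", id, "study_activity"), "<masked>")
  expect_equal(enforce_access(reg, "root", id, "project"), "P")
  expect_null(enforce_access(reg, "bob", id, "absent_field"))
  expect_error(enforce_access(reg, "nobody", id, "project"), "unknown user")
})

test_that("the audit log replays to the live entity statuses", {
  reg <- new_registry()
  a <- register_one(reg, "CCO")
  b <- register_one(reg, "CCC")
  reassign_batch(reg, "reg1", a$batch_code, "CCC")
  archive_batch(reg, "reg1", b$batch_code)
  st <- replay_audit(reg)
  for (k in seq_len(nrow(reg$molecules)))
    expect_equal(unname(st[paste0("molecule:", reg$molecules$code[k])]),
                 reg$molecules$status[k])
  for (k in seq_len(nrow(reg$substances)))
    expect_equal(unname(st[paste0("substance:", reg$substances$code[k])]),
                 reg$substances$status[k])
  for (k in seq_len(nrow(reg$batches)))
    expect_equal(unname(st[paste0("batch:", reg$batches$code[k])]),
                 reg$batches$status[k])
})

test_that("registries survive a JSON save/load round trip", {
  reg <- new_registry()
  register_one(reg, "N#CCC(=O)O",
               composition = substance_composition(
                 data.frame(id = "sodium", coeff = 1)))
  path <- tempfile(fileext = ".json")
  save_registry(reg, path)
  back <- load_registry(path)
  expect_equal(molecules(back), molecules(reg))
  expect_equal(substances(back), substances(reg))
  expect_equal(batches(back), batches(reg))
  expect_equal(back$next_batch, reg$next_batch)
  # and it keeps working: the same structure still dedupes
  add_user(back, "extra", "registrar")
  r <- decide_submission(back, "extra",
                         submit(back, "extra", "OC(=O)CC#N",
                                metadata = meta_ok()), "approve")
  expect_equal(r$molecule_code, molecules(reg)$code[1])
})
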