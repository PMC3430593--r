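test_that("the 10-record fixture imports to 9 batches, 1 reject, 7 molecules", {
  fx <- generate_fixtures(42, c(clean = 7, valence_error = 1, duplicate = 2))
  reg <- new_registry()
  rep <- import_sdf(reg, fx$path, "reg1")
  expect_equal(rep$total, 10L)
  expect_equal(rep$registered + rep$registered_with_warnings, 9L)
  expect_equal(rep$rejected, 1L)
  expect_equal(nrow(molecules(reg)), 7L)
  expect_equal(nrow(batches(reg)), 9L)
  # disposition conservation
  expect_equal(rep$registered + rep$registered_with_warnings + rep$rejected +
                 rep$submitted, rep$total)
})

test_that("import respects the manifest's expectations and collapse groups", {
  fx <- generate_fixtures(9, c(clean = 5, fixable = 3, valence_error = 1,
                               stereo_error = 1, duplicate = 2, tautomer = 2,
                               salt_variant = 2, no_structure = 2))
  reg <- new_registry()
  rep <- import_sdf(reg, fx$path, "reg1")
  man <- merge(fx$manifest, rep$dispositions, by = "record")
  expect_equal(man$outcome, man$expected)
  # records sharing a collapse group land under one molecule code
  reg_rows <- man[!is.na(man$molecule_code), ]
  per_group <- tapply(reg_rows$molecule_code, reg_rows$group,
                      function(x) length(unique(x)))
  expect_true(all(per_group == 1L))
  # distinct groups get distinct codes, except never-merging No Structure
  ns_groups <- unique(man$group[man$category == "no_structure"])
  chem <- reg_rows[!(reg_rows$group %in% ns_groups), ]
  expect_equal(length(unique(chem$molecule_code)),
               length(unique(chem$group)))
  # salt variants: one molecule, two substances
  sv <- man[man$category == "salt_variant" & man$group ==
              man$group[man$category == "salt_variant"][1], ]
  expect_equal(length(unique(sv$molecule_code)), 1L)
  expect_equal(length(unique(sv$substance_code)), 2L)
})

test_that("empty SDF imports to an empty report", {
  p <- tempfile(fileext = ".sdf")
  writeLines(character(0), p)
  reg <- new_registry()
  rep <- import_sdf(reg, p, "reg1")
  expect_equal(rep$total, 0L)
  expect_error(import_sdf(reg, "/nonexistent/x.sdf", "reg1"), "cannot read")
})

test_that("re-import never creates molecules, only batches", {
  fx <- generate_fixtures(13, c(clean = 5, duplicate = 1))
  reg <- new_registry()
  import_sdf(reg, fx$path, "reg1")
  m1 <- nrow(molecules(reg)); b1 <- nrow(batches(reg))
  import_sdf(reg, fx$path, "reg1")
  expect_equal(nrow(molecules(reg)), m1)
  expect_equal(nrow(batches(reg)), b1 + 6L)
})

test_that("bulk import and manual submission assign identical codes", {
  fx <- generate_fixtures(21, c(clean = 4))
  regA <- new_registry()
  repA <- import_sdf(regA, fx$path, "reg1")
  regB <- new_registry()
  for (rec in read_sdf(fx$path)) {
    id <- submit(regB, "sub1", rec$structure, metadata = meta_ok())
    decide_submission(regB, "reg1", id, "approve")
  }
  expect_equal(molecules(regA)$code, molecules(regB)$code)
  expect_equal(molecules(regA)$ucd_key, molecules(regB)$ucd_key)
  expect_equal(substances(regA)$code, substances(regB)$code)
})

test_that("without auto-approve records wait in the submission area", {
  fx <- generate_fixtures(31, c(clean = 3))
  reg <- new_registry()
  rep <- import_sdf(reg, fx$path, "sub1", auto_approve = FALSE)
  expect_equal(rep$submitted, 3L)
  expect_equal(nrow(molecules(reg)), 0L)
  expect_equal(nrow(submissions(reg)), 3L)
  # a submitter may not auto-approve
  expect_error(import_sdf(reg, fx$path, "sub1", auto_approve = TRUE),
               "registrar")
})

test_that("export writes one record per batch and round-trips the registry", {
  reg <- new_registry()
  r <- register_one(reg, "N#CCC(=O)O")
  register_one(reg, "N#CCC(=O)O",
               composition = substance_composition(
                 data.frame(id = "sodium", coeff = 1)))
  register_one(reg, "N#CCC(=O)O",
               composition = substance_composition(
                 data.frame(id = "sodium", coeff = 1)))
  v <- stereo_variants()$and_grp
  register_one(reg, v, mixture_ratio = c(30, 70))
  id_ns <- submit(reg, "sub1", no_structure = TRUE, metadata = meta_ok())
  decide_submission(reg, "reg1", id_ns, "approve")
  out <- tempfile(fileext = ".sdf")
  export_sdf(reg, out)
  expect_length(read_sdf(out), 5L)         # one record per batch

  reg2 <- new_registry()
  import_sdf(reg2, out, "reg1")
  expect_equal(nrow(molecules(reg2)), nrow(molecules(reg)))
  expect_equal(nrow(substances(reg2)), nrow(substances(reg)))
  expect_equal(nrow(batches(reg2)), nrow(batches(reg)))
  expect_setequal(molecules(reg2)$ucd_key, molecules(reg)$ucd_key)
  expect_setequal(substances(reg2)$comp_key, substances(reg)$comp_key)

  # archived-only selection exports nothing
  reg3 <- new_registry()
  r3 <- register_one(reg3, "CCO")
  archive_batch(reg3, "reg1", r3$batch_code)
  expect_warning(n <- export_sdf(reg3, tempfile(fileext = ".sdf")), "empty")
  expect_equal(n, 0L)
})
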