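test_that("compound validation enforces invariants and names offending fields", {
  expect_s3_class(onecpt_drug(), "compound_model")

  # negative rate -> validation error naming the field
  err <- expect_error(
    compound_model("bad", 400, 0.1, ka = -1, vss = 1, cl_renal = 1),
    class = "pbpkddi_validation_error")
  expect_match(conditionMessage(err), "ka")

  # missing mandatory field -> schema error naming the field
  err <- expect_error(
    compound_from_list(list(name = "x", fu_plasma = 0.1)),
    class = "pbpkddi_schema_error")
  expect_match(conditionMessage(err), "mol_weight")

  # all clearances zero -> no elimination pathway
  expect_error(
    compound_model("noelim", 400, 0.1, ka = 1, vss = 1),
    class = "pbpkddi_validation_error")

  # unknown enzyme id rejected
  expect_error(
    compound_model("badenz", 400, 0.1, ka = 1, vss = 1,
                   enzyme_clearances = list(
                     CYP9Z9 = list(value = 1, units = "uL/min/pmol"))),
    class = "pbpkddi_schema_error")

  # fractions outside (0, 1]
  expect_error(
    compound_model("badfu", 400, 1.2, ka = 1, vss = 1, cl_renal = 1),
    class = "pbpkddi_validation_error")
})

test_that("transporter parameters are parsed but flagged inactive", {
  expect_message(
    compound_model("tx", 400, 0.1, ka = 1, vss = 1, cl_renal = 1,
                   transporters = list(OATP1B1 = list(ki = 1))),
    class = "pbpkddi_transporters_inactive")
})

test_that("config round-trip through YAML and JSON is value-identical", {
  for (ext in c("yaml", "json")) {
    for (nm in c("fedratinib", "ketoconazole", "midazolam")) {
      cm <- suppressMessages(compound_library(nm)[[1]])
      f <- withr::local_tempfile(fileext = paste0(".", ext))
      write_compound(cm, f)
      back <- suppressMessages(load_compound(f))
      f2 <- withr::local_tempfile(fileext = paste0(".", ext))
      write_compound(back, f2)
      back2 <- suppressMessages(load_compound(f2))
      expect_equal(unclass(back2), unclass(back), ignore_attr = TRUE)
      # numeric fields of the shipped fixture survive exactly
      expect_identical(back$mol_weight, cm$mol_weight)
      expect_identical(back$vss, cm$vss)
      for (e in names(cm$enzyme_clearances))
        expect_identical(back$enzyme_clearances[[e]]$value,
                         cm$enzyme_clearances[[e]]$value)
    }
  }
})

test_that("built-in library is complete and valid", {
  lib <- compound_library()
  expected <- c("fedratinib", "ketoconazole", "itraconazole", "erythromycin",
                "diltiazem", "fluconazole", "efavirenz", "rifampin",
                "midazolam", "omeprazole", "metoprolol", "repaglinide",
                "warfarin")
  expect_setequal(names(lib), expected)
  for (cm in lib) {
    expect_s3_class(validate_compound(cm), "compound_model")
    expect_true(nzchar(cm$provenance))
    for (ik in cm$interactions) expect_true(nzchar(ik$provenance))
  }
  # ketoconazole: reversible CYP3A4 inhibition, no TDI
  k <- lib$ketoconazole$interactions$CYP3A4_liver
  expect_gt(k$ki_reversible, 0)
  expect_null(k$kinact)
  # warfarin metabolism is CYP2C9-dominated
  expect_true("CYP2C9" %in% names(lib$warfarin$enzyme_clearances))
  s <- simulate_pk(central_subject(), lib$warfarin,
                   regimen("warfarin", 15, "single", 0), 240)
  fm <- fm_fe_partition(s, c(0, 240))
  expect_gt(fm[["CYP2C9"]], 0.8)
  # fedratinib: four metabolic + gut + renal + biliary pathways
  fed <- lib$fedratinib
  expect_setequal(names(fed$enzyme_clearances),
                  c("CYP3A4_liver", "CYP2C19", "CYP2D6", "HLM_additional"))
  expect_identical(fed$fg_model$type, "gut_extraction")
  expect_gt(fed$cl_renal, 0)
  expect_gt(fed$cl_biliary, 0)
  # subsetting and unknown names
  expect_length(compound_library(c("midazolam", "warfarin")), 2)
  expect_error(compound_library("nosuchdrug"), class = "pbpkddi_schema_error")
})
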