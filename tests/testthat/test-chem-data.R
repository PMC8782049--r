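test_that("packaged fixture tables have the published shape", {
  tabs <- fixture_tables()

  expect_s3_class(tabs$table1, "compound_set")
  expect_equal(length(tabs$table1), 31L)

  expect_s3_class(tabs$table2, "thermo_table")
  expect_equal(nrow(tabs$table2), 6L)
  expect_equal(tabs$table2$compound_id[c(1L, 6L)],
               c("pyridine", "succinimide"))

  expect_equal(nrow(tabs$table3), 22L)
  expect_equal(nrow(tabs$table4), 21L)
  expect_equal(tabs$table4$delta_e[tabs$table4$compound_id == "uracil"], -1200)

  # sentinel semantics: "-" rows may later receive predictions, "N/A" not
  lit <- tabs$table1$literature
  expect_setequal(unique(lit$status),
                  c("measured", "not_reported", "no_proton"))
  ur <- lit[lit$compound_id == "uracil", ]
  expect_equal(ur$status[ur$step == "pKa1"], "not_reported")
  py <- lit[lit$compound_id == "pyridine", ]
  expect_equal(py$status[py$step == "pKa2"], "no_proton")

  # external predictions carry the printed uncertainties
  ext <- tabs$table1$external
  az <- ext[ext$compound_id == "azauracil" & ext$step == "pKa1", ]
  expect_equal(az$value, -4.4)
  expect_equal(az$uncertainty, 0.2)

  # transcription checksums over the numeric fixture columns
  expect_equal(sum(tabs$table2$exp_drG), 9195)
  expect_equal(sum(tabs$table2$calc_drG), 9184)
  expect_equal(sum(tabs$table3$delta_e), -25529)
  expect_equal(sum(tabs$table4$delta_e), -25971)
  expect_equal(sum(tabs$table3$exp, na.rm = TRUE), 100.82)
  expect_equal(sum(tabs$table4$exp, na.rm = TRUE), 118)
})

test_that("load_dataset dispatches on schema and enforces invariants", {
  tmp <- withr::local_tempdir()

  # header-only file -> empty collection
  empty <- file.path(tmp, "empty.csv")
  writeLines("no,compound_id,name,formula,formula_note,pka1_values,pka1_sources,acd_pka1,acd_pka1_unc,pka2_values,pka2_sources,acd_pka2,acd_pka2_unc",
             empty)
  expect_equal(length(load_dataset(empty)), 0L)

  # malformed numeric cell -> parse error naming line and column
  bad <- file.path(tmp, "bad.csv")
  writeLines(c("compound_id,exp_drG,calc_drG,calc_dE",
               "pyridine,1601,1605,1648",
               "pyrazine,16O5,1605,1643"), bad)
  expect_error(load_dataset(bad), "line 3.*column 'exp_drG'")

  # duplicate microstate key -> validation error
  dup <- file.path(tmp, "dup.csv")
  writeLines(c("compound_id,charge,tautomer_id,phase,energy",
               "u,0,t01,aqueous,-100",
               "u,0,t01,aqueous,-101"), dup)
  expect_error(load_dataset(dup), "duplicate microstate key")

  # implausible experimental value in the compendium format is rejected
  crazy <- file.path(tmp, "crazy.csv")
  writeLines(c("compound_id,name,formula,pka1_values,pka1_sources,acd_pka1,acd_pka1_unc,pka2_values,pka2_sources,acd_pka2,acd_pka2_unc",
               "x,x,XH,99,1,-,,-,,-,"), crazy)
  expect_error(load_dataset(crazy), "plausible range")
})

test_that("hartree energies are converted on load", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "ms.csv")
  writeLines(c("compound_id,charge,tautomer_id,phase,energy,unit",
               "u,0,t01,aqueous,-1,hartree",
               "u,-1,t01,aqueous,-2625.5,kJ/mol"), f)
  ms <- read_microstates(f)
  expect_equal(ms$energy, c(-2625.5, -2625.5))
})

test_that("datasets round-trip through CSV and JSON losslessly", {
  ds <- simulate_pka_dataset(n_compounds = 6, seed = 42)

  tmp <- withr::local_tempdir()
  for (fmt in c("csv", "json")) {
    path <- file.path(tmp, if (fmt == "csv") "ds" else "ds.json")
    write_dataset(ds, path, fmt)
    back <- load_dataset(path, fmt)
    expect_identical(back$compounds$compound_id, ds$compounds$compound_id)
    expect_identical(back$microstates$tautomer_id, ds$microstates$tautomer_id)
    expect_identical(back$microstates$charge, ds$microstates$charge)
    expect_equal(back$microstates$energy, ds$microstates$energy,
                 tolerance = 1e-12)
    expect_equal(back$literature$value, ds$literature$value,
                 tolerance = 1e-12)
  }

  thermo <- fixture_tables()$table2
  jf <- file.path(tmp, "thermo.json")
  write_dataset(thermo, jf, "json")
  expect_equal(as.data.frame(load_dataset(jf)), as.data.frame(thermo))
})

test_that("structural validation rejects malformed components", {
  cmp <- data.frame(compound_id = "a", name = "a", formula = "AH")
  expect_error(compound_set(cmp, microstates = make_ensemble(NaN)), "finite")
  expect_error(
    compound_set(cmp, microstates = transform(make_ensemble(-1), charge = 2L)),
    "charge")
  expect_error(
    compound_set(cmp, literature = data.frame(compound_id = "a", step = "pKa3",
                                              value = 1)),
    "step")
  expect_error(
    compound_set(rbind(cmp, cmp)), "duplicate compound_id")
})
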