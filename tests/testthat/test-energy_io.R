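test_that("the packaged QM3 table loads as nine unique stationary points", {
  tab <- load_species_table(packaged_fixtures()[["table2_qm3_absolute"]],
                            model_charge = -2)
  expect_s3_class(tab, "species_table")
  expect_equal(nrow(tab), 9)
  expect_equal(unique(tab$model), "QM3")
  expect_equal(tab$label,
               c("ES", "TS1", "IM1", "IM2", "TS2", "PC2", "IM3", "TS3", "PC3"))
  expect_equal(tab$energy_au[tab$label == "ES"], -6018.936815)
  # three species per elementary step, three steps
  expect_equal(as.vector(table(tab$step)), c(3L, 3L, 3L))
  expect_setequal(unique(tab$step), CYCLE_STEPS)
})

test_that("table loading enforces schema, uniqueness and parseability", {
  f <- withr::local_tempfile(fileext = ".tsv")

  # empty body with a valid header -> empty collection
  writeLines("label\tstep\tmodel\tfunctional\tbasis\tsolvent\tenergy_au", f)
  expect_equal(nrow(load_species_table(f)), 0)

  # missing required column is named in the error
  writeLines(c("label\tstep\tmodel\tfunctional\tbasis\tenergy_au",
               "RC\tfructosylation\tQM3\tB3LYP\t6-31+G(d)\t-1.0"), f)
  expect_error(load_species_table(f), "solvent")

  # duplicate (label, step, model, method) is a conflict
  writeLines(c("label\tstep\tmodel\tfunctional\tbasis\tsolvent\tenergy_au",
               "ES\tfructosylation\tQM3\tB3LYP\tb\ts\t-1.0",
               "ES\tfructosylation\tQM3\tB3LYP\tb\ts\t-2.0"), f)
  expect_error(load_species_table(f), "duplicate")

  # unparseable energy reports the offending line
  writeLines(c("label\tstep\tmodel\tfunctional\tbasis\tsolvent\tenergy_au",
               "RC\tfructosylation\tQM3\tB3LYP\tb\ts\t-1.0",
               "TS1\tfructosylation\tQM3\tB3LYP\tb\ts\tnot-a-number"), f)
  expect_error(load_species_table(f), "line 3")

  # declared-charge mismatch is caught
  writeLines(c(
    "label\tstep\tmodel\tfunctional\tbasis\tsolvent\tenergy_au\tcharge",
    "RC\tfructosylation\tQM3\tB3LYP\tb\ts\t-1.0\t0"), f)
  expect_error(load_species_table(f, model_charge = -2), "charge")
})

test_that("numeric parsing is delimiter- and whitespace-insensitive", {
  ref <- load_species_table(packaged_fixtures()[["table2_qm3_absolute"]])
  f <- withr::local_tempfile(fileext = ".csv")
  # re-serialize as CSV with ragged padding around fields
  body <- vapply(seq_len(nrow(ref)), function(i) {
    paste(c(sprintf("  %s ", ref$label[i]), ref$step[i], ref$model[i],
            ref$functional[i], ref$basis[i], ref$solvent[i],
            sprintf("   %s", formatC(ref$energy_au[i], format = "f",
                                     digits = 6)),
            ref$charge[i]), collapse = ",")
  }, character(1))
  writeLines(c("label,step,model,functional,basis,solvent,energy_au,charge",
               body), f)
  again <- load_species_table(f)
  expect_equal(again$energy_au, ref$energy_au)
  expect_equal(trimws(again$label), ref$label)
})

test_that("Gaussian-style logs parse with last-energy-wins semantics", {
  log <- c(" SCF Done:  E(RB3LYP) =  -683.100000000     A.U. after    9 cycles",
           " some chatter",
           " SCF Done:  E(RB3LYP) =  -683.300000000     A.U. after    3 cycles")
  rec <- parse_qc_log(text = log)
  expect_equal(rec$final_energy_au, -683.3)
  expect_length(rec$frequencies_cm1, 0)

  # no energy line at all is an error
  expect_error(parse_qc_log(text = " Frequencies --   100.0"), "SCF Done")

  # malformed frequency line reports its line number
  bad <- c(" SCF Done:  E(RB3LYP) =  -1.0     A.U. after 1 cycles",
           " Frequencies --   100.0   oops   300.0")
  expect_error(parse_qc_log(text = bad), "line 2")
})

test_that("log parsing recovers frequencies, thermal block and metadata", {
  rec <- qc_record(
    final_energy_au = -683.301,
    frequencies_cm1 = c(-250, 100, 500, 1500.1234),
    thermal_corrections = list(zpe = 0.123456, enthalpy = 0.130944,
                               gibbs = 0.09),
    dielectric = 80, mass_amu = 180.156,
    rotational_constants_ghz = c(1.2345678, 0.9876543, 0.7654321),
    symmetry_number = 1, charge = 0, multiplicity = 1)
  back <- parse_qc_log(text = write_qc_log(rec))
  expect_equal(back$final_energy_au, rec$final_energy_au)
  expect_equal(back$frequencies_cm1, rec$frequencies_cm1)
  expect_equal(back$thermal_corrections$zpe, 0.123456)
  expect_equal(back$thermal_corrections$gibbs, 0.09)
  expect_equal(back$dielectric, 80)
  expect_equal(back$mass_amu, 180.156)
  expect_equal(back$rotational_constants_ghz, rec$rotational_constants_ghz)
  expect_equal(back$symmetry_number, 1L)
  expect_equal(back$multiplicity, 1L)
})

test_that("qc_record enforces its invariants", {
  expect_error(qc_record(-1, dielectric = 0.9), "dielectric")
  expect_error(qc_record(-1, frequencies_cm1 = rep(100, 10), n_atoms = 3),
               "3N-5")
  expect_silent(qc_record(-1, frequencies_cm1 = rep(100, 4), n_atoms = 3))
})

test_that("profile documents round-trip field-for-field", {
  steps <- fixture_steps_qm3()
  jn <- junction_spec("IM2", delta_g_diss = 3.1)
  wp <- stitch_bras(steps$fructosylation,
                    list(steps$hydrolysis, steps$transfructosylation), jn)
  f <- withr::local_tempfile(fileext = ".yml")
  write_profile_document(wp, f)
  back <- read_profile_document(f)
  expect_equal(as.data.frame(back), as.data.frame(wp))
  expect_equal(attr(back, "provenance")$procedure, "bras")
  expect_equal(attr(back, "steps"), attr(wp, "steps"))
  # RC entry of a stitched profile is exactly zero in the document
  expect_identical(back$energy_kcal[back$label == "RC"], 0)

  # unicode labels survive
  pts <- data.frame(label = c("RC", "TS‡", "IMα"),
                    branch = "common", energy_kcal = c(0, 12.5, -3.25))
  wp2 <- whole_profile(pts, provenance = list(method = "m", model = "QM",
                                              procedure = "bras"))
  f2 <- withr::local_tempfile(fileext = ".yml")
  write_profile_document(wp2, f2)
  expect_equal(as.data.frame(read_profile_document(f2)), pts,
               ignore_attr = TRUE)
})
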