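table3 <- function() utils::read.delim(packaged_fixtures()[["table3_barriers"]])
table5 <- function() utils::read.delim(packaged_fixtures()[["table5_bras"]])

test_that("the dissociation-corrected junction places the second half", {
  # B3LYP/QM2: hydrolysis step barrier 17.6 with junction offset 3.2
  first <- step_from_barriers("fructosylation", "RC", "TS1", "IM1",
                              barrier = 17.5, reaction = 0.1)
  hyd <- step_from_barriers("hydrolysis", "IM2", "TS2", "PC2",
                            barrier = 17.6, reaction = -13.0)
  trn <- step_from_barriers("transfructosylation", "IM3", "TS3", "PC3",
                            barrier = 23.0, reaction = 8.3)
  jn <- junction_spec("IM2", offset_kcal = 3.2)
  wp <- stitch_bras(first, list(hyd, trn), jn)
  expect_equal(overall_barrier(wp, "hydrolysis"), 20.8)
  # the SAME offset places the transfructosylation TS
  expect_equal(overall_barrier(wp, "transfructosylation"), 26.2)
  expect_identical(wp$energy_kcal[wp$label == "RC"], 0)

  # component form: dE(IM1 rel RC) read off the first half + dG_diss
  jn2 <- junction_spec("IM2", delta_g_diss = 3.1)
  wp2 <- stitch_bras(first, list(hyd, trn), jn2)
  expect_equal(overall_barrier(wp2, "hydrolysis"), 0.1 + 3.1 + 17.6)
  expect_equal(overall_reaction_energy(wp2, "hydrolysis"), 0.1 + 3.1 - 13.0)

  # inconsistent explicit components are rejected
  expect_error(junction_spec("IM2", offset_kcal = 5, delta_e_donor = 1,
                             delta_g_diss = 3.1), "exactly")
  expect_error(junction_spec("IM2"), "offset_kcal")
  # junction referencing an absent donor
  expect_error(stitch_bras(first, hyd,
                           junction_spec("IM2", donor_species = "IMX",
                                         offset_kcal = 1)),
               "donor")
})

test_that("a null junction reduces stitching to plain concatenation", {
  first <- step_from_barriers("fructosylation", "RC", "TS1", "IM1",
                              barrier = 10, reaction = 2)
  hyd <- step_from_barriers("hydrolysis", "IM2", "TS2", "PC2",
                            barrier = 7, reaction = -1)
  wp <- stitch_bras(first, hyd, junction_spec("IM2", offset_kcal = 0))
  expect_equal(wp$energy_kcal,
               c(0, 10, 2, 0, 7, -1))
})

test_that("junction offset calibration inverts the stitching identity", {
  expect_equal(calibrate_junction_offset(20.8, 17.6), 3.2)
  expect_equal(calibrate_junction_offset(5, 5), 0)
  expect_equal(calibrate_junction_offset(24.9, 22.6), 2.3)
})

test_that("shifting the offset moves only the second half, rigidly", {
  first <- step_from_barriers("fructosylation", "RC", "TS1", "IM1",
                              barrier = 17.5, reaction = 0.1)
  hyd <- step_from_barriers("hydrolysis", "IM2", "TS2", "PC2",
                            barrier = 17.6, reaction = -13.0)
  for (shift in c(-4, 0.25, 9)) {
    a <- stitch_bras(first, hyd, junction_spec("IM2", offset_kcal = 3.2))
    b <- stitch_bras(first, hyd, junction_spec("IM2", offset_kcal = 3.2 + shift))
    common <- a$branch == "common"
    expect_identical(b$energy_kcal[common], a$energy_kcal[common])
    expect_equal(b$energy_kcal[!common], a$energy_kcal[!common] + shift)
  }
})

test_that("one junction per functional reproduces both published branches", {
  t3 <- table3(); t5 <- table5()
  for (i in seq_len(nrow(t3))) {
    off <- calibrate_junction_offset(t5$act_hydrolysis[i], t3$dE2[i])
    first <- step_from_barriers("fructosylation", "RC", "TS1", "IM1",
                                barrier = t3$dE1[i])
    hyd <- step_from_barriers("hydrolysis", "IM2", "TS2", "PC2",
                              barrier = t3$dE2[i])
    trn <- step_from_barriers("transfructosylation", "IM3", "TS3", "PC3",
                              barrier = t3$dE3[i])
    wp <- stitch_bras(first, list(hyd, trn),
                      junction_spec("IM2", offset_kcal = off))
    expect_equal(overall_barrier(wp, "hydrolysis"), t5$act_hydrolysis[i],
                 tolerance = 1e-12)
    expect_lt(abs(overall_barrier(wp, "transfructosylation") -
                    t5$act_transfructosylation[i]), 0.1 + 1e-9)
    # difference identity: branch TS difference equals the step-level
    # selectivity exactly (the shared offset cancels)
    expect_equal(overall_barrier(wp, "transfructosylation") -
                   overall_barrier(wp, "hydrolysis"),
                 selectivity_dd(t3$dE2[i], t3$dE3[i]), tolerance = 1e-12)
  }
})

test_that("step-level selectivity is the published ddE column", {
  expect_equal(selectivity_dd(17.6, 23.0), 5.4)
  expect_equal(selectivity_dd(20.0, 27.0), 7.0)
  expect_equal(selectivity_dd(4, 4), 0)
})

test_that("the balanced ledger reduces to plain relative energies when empty", {
  steps <- fixture_steps_qm3()
  tab <- load_species_table(packaged_fixtures()[["table2_qm3_absolute"]])
  hyd <- as.data.frame(tab[tab$step == "hydrolysis", ])
  wp <- stitch_balanced(species_table(hyd), reference_state = "IM2")
  expect_equal(stats::setNames(wp$energy_kcal, wp$label),
               steps$hydrolysis$relative_kcal)
})

test_that("a one-sided auxiliary water enters the ledger sum as written", {
  # two-state toy: B's side carries one explicit water molecule
  states <- species_table(data.frame(
    label = c("RC", "PC2"), step = c("fructosylation", "hydrolysis"),
    model = "toy", functional = "F", basis = "B", solvent = "S",
    energy_au = c(-100.0, -176.45)))
  ledger <- data.frame(state = "RC", aux = "water",
                       energy_au = -76.4, count = 1)
  wp <- stitch_balanced(states, ledger, reference_state = "RC")
  # hand arithmetic: [(-176.45) - (-100.0 - 76.4)] * 627.5095
  expect_equal(wp$energy_kcal[wp$label == "PC2"],
               (-176.45 - (-176.4)) * 627.5095, tolerance = 1e-9)

  # declared compositions: balance holds with the water, fails without it
  comps <- c(RC = "C6H12O6", PC2 = "C6H14O7", water = "H2O")
  expect_silent(stitch_balanced(states, ledger, "RC", compositions = comps))
  expect_error(stitch_balanced(states, NULL, "RC", compositions = comps),
               "imbalance")
})

test_that("auxiliaries present identically on all states cancel", {
  for (seed in 1:10) {
    set.seed(seed)
    tab <- make_cycle_energies(cycle_blueprint(noise_kcal = 0.3, seed = seed))
    one_step <- species_table(as.data.frame(tab[tab$step == "hydrolysis", ]))
    plain <- stitch_balanced(one_step, reference_state = "IM2")
    aux_e <- runif(1, -80, -10)
    ledger <- data.frame(state = one_step$label, aux = "aux",
                         energy_au = aux_e, count = 2)
    with_aux <- stitch_balanced(one_step, ledger, reference_state = "IM2")
    expect_equal(with_aux$energy_kcal, plain$energy_kcal, tolerance = 1e-6)
  }
})

test_that("derived profile quantities validate their structure", {
  first <- step_from_barriers("fructosylation", "RC", "TS1", "IM1",
                              barrier = 17.5, reaction = 0.1)
  hyd <- step_from_barriers("hydrolysis", "IM2", "TS2", "PC2",
                            barrier = 17.6, reaction = -13.0)
  wp <- stitch_bras(first, hyd, junction_spec("IM2", offset_kcal = 3.2))
  expect_error(overall_barrier(wp, "transfructosylation"), "branch")
  expect_equal(overall_reaction_energy(wp, "hydrolysis"), 3.2 - 13.0)

  # span mode: here no intermediate dips below RC, so span equals TS height
  expect_equal(overall_barrier(wp, "hydrolysis", mode = "span"), 20.8)
  # with a deep pre-TS minimum the span exceeds the TS-relative-to-RC value
  pts <- data.frame(label = c("RC", "TS1", "IM1", "IM2", "TS2", "PC2"),
                    branch = c(rep("common", 3), rep("hydrolysis", 3)),
                    energy_kcal = c(0, 10, -8, -8, 9, -20))
  deep <- whole_profile(pts, provenance = list(procedure = "manual"))
  expect_equal(overall_barrier(deep, "hydrolysis", mode = "ts"), 9)
  expect_equal(overall_barrier(deep, "hydrolysis", mode = "span"), 17)
})

test_that("the rate-limiting step is the highest TS relative to RC", {
  first <- step_from_barriers("fructosylation", "RC", "TS1", "IM1",
                              barrier = 17.5, reaction = 0.1)
  hyd <- step_from_barriers("hydrolysis", "IM2", "TS2", "PC2",
                            barrier = 17.6, reaction = -13.0)
  wp <- stitch_bras(first, hyd, junction_spec("IM2", offset_kcal = 3.2))
  # TS1 at 17.5, TS2 at 20.8 -> the deglycosylation (hydrolysis) step limits
  rls <- rate_limiting_step(wp, "hydrolysis")
  expect_equal(rls$step, "hydrolysis")
  expect_equal(rls$ts_label, "TS2")
  expect_equal(rls$energy_kcal, 20.8)
  expect_false(rls$tie)

  # raising TS1 above TS2 flips the limiting step
  first_hi <- step_from_barriers("fructosylation", "RC", "TS1", "IM1",
                                 barrier = 25, reaction = 0.1)
  wp2 <- stitch_bras(first_hi, hyd, junction_spec("IM2", offset_kcal = 3.2))
  expect_equal(rate_limiting_step(wp2, "hydrolysis")$step, "fructosylation")

  # equal TS heights are reported as a tie
  hyd_tie <- step_from_barriers("hydrolysis", "IM2", "TS2", "PC2",
                                barrier = 17.5, reaction = -13.0)
  wp3 <- stitch_bras(first, hyd_tie, junction_spec("IM2", offset_kcal = 0))
  rls3 <- rate_limiting_step(wp3, "hydrolysis")
  expect_true(rls3$tie)
  expect_setequal(rls3$step, c("fructosylation", "hydrolysis"))
})
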