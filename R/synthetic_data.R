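# Synthetic ground-truth generators: species-energy sets with prescribed
# barriers, Gaussian-style logs with known content, and the packaged
# transcribed fixtures.

#' Blueprint for a synthetic two-branch catalytic cycle
#'
#' Prescribes every quantity the analysis pipeline is meant to recover:
#' the three step barriers, the glycosyl-enzyme intermediate's placement
#' relative to RC, the dissociation free energy used at the junction, and
#' the per-branch reaction energies. Defaults mirror the reported
#' B3LYP/QM2 conditions (dE1 17.5, dE2 17.6, dE3 23.0 kcal/mol,
#' dG_diss 3.1, overall hydrolysis/transfructosylation activation 20.8 and
#' 26.2 relative to RC). The three steps carry deliberately different base
#' absolute energies near -6000 hartree, so compositions differ and
#' stitching is genuinely required, and the arithmetic runs at
#' catastrophic-cancellation scale.
#'
#' @param dE1,dE2,dE3 step barriers, kcal/mol.
#' @param dE_im1 IM1 energy relative to RC, kcal/mol.
#' @param dG_diss dissociation free energy at the junction, kcal/mol.
#' @param rxn_hydrolysis,rxn_transfructosylation per-step reaction energies
#'   (PC relative to the step's IM), kcal/mol.
#' @param base_energies named numeric: absolute base energy (hartree) of
#'   each step's composition.
#' @param noise_kcal Gaussian noise s.d. applied independently to every
#'   absolute energy, kcal/mol (0 = exact).
#' @param seed integer random seed.
#' @param functional,model,basis,solvent provenance strings.
#' @return object of class `cycle_blueprint`.
#' @export
cycle_blueprint <- function(dE1 = 17.5, dE2 = 17.6, dE3 = 23.0,
                            dE_im1 = 0.1, dG_diss = 3.1,
                            rxn_hydrolysis = -13.0,
                            rxn_transfructosylation = 8.3,
                            base_energies = c(
                              fructosylation = -6018.94,
                              hydrolysis = -5943.23,
                              transfructosylation = -6094.61),
                            noise_kcal = 0, seed = 1,
                            functional = "B3LYP", model = "QM2",
                            basis = "6-311+G(2d,2p)", solvent = "cpcm80") {
  if (noise_kcal < 0) stop("noise_kcal must be >= 0", call. = FALSE)
  stopifnot(setequal(names(base_energies), CYCLE_STEPS))
  structure(list(
    dE1 = dE1, dE2 = dE2, dE3 = dE3, dE_im1 = dE_im1, dG_diss = dG_diss,
    rxn_hydrolysis = rxn_hydrolysis,
    rxn_transfructosylation = rxn_transfructosylation,
    base_energies = base_energies, noise_kcal = noise_kcal, seed = seed,
    functional = functional, model = model, basis = basis, solvent = solvent
  ), class = "cycle_blueprint")
}

#' Generate a species-energy table from a cycle blueprint
#'
#' Constructs the nine absolute electronic energies so that each step's
#' internal differences equal the prescribed barriers/reaction energies
#' (plus optional Gaussian noise). With zero noise, running the table
#' through [relative_energies()] and [stitch_bras()] (junction components
#' `dE_im1 + dG_diss`) recovers every prescribed quantity exactly.
#'
#' @param blueprint a [cycle_blueprint()].
#' @return a [species_table()] with nine rows (RC..PC3).
#' @export
make_cycle_energies <- function(blueprint) {
  stopifnot(inherits(blueprint, "cycle_blueprint"))
  bp <- blueprint
  k <- .const$hartree_kcal
  rel <- list(
    fructosylation = c(RC = 0, TS1 = bp$dE1, IM1 = bp$dE_im1),
    hydrolysis = c(IM2 = 0, TS2 = bp$dE2, PC2 = bp$rxn_hydrolysis),
    transfructosylation = c(IM3 = 0, TS3 = bp$dE3,
                            PC3 = bp$rxn_transfructosylation)
  )
  rows <- do.call(rbind, lapply(CYCLE_STEPS, function(s) {
    data.frame(label = names(rel[[s]]), step = s,
               energy_au = bp$base_energies[[s]] + rel[[s]] / k,
               stringsAsFactors = FALSE)
  }))
  if (bp$noise_kcal > 0) {
    set.seed(bp$seed)
    rows$energy_au <- rows$energy_au +
      stats::rnorm(nrow(rows), sd = bp$noise_kcal) / k
  }
  rows$model <- bp$model
  rows$functional <- bp$functional
  rows$basis <- bp$basis
  rows$solvent <- bp$solvent
  rows$charge <- -2L
  species_table(rows[, c("label", "step", "model", "functional", "basis",
                         "solvent", "energy_au", "charge")],
                model_charge = -2L)
}

#' Write a qc_record as a Gaussian-style text log
#'
#' Emits the dialect accepted by [parse_qc_log()]: an `SCF Done:` energy
#' line, `Frequencies --` triplet blocks (imaginary modes as negative
#' wavenumbers; the block is omitted when there are no frequencies),
#' thermal-correction lines, and metadata lines for dielectric, mass,
#' rotational constants, symmetry number, and charge/multiplicity.
#' Numbers are printed at the dialect's native precision (energies 9
#' decimals, frequencies 4), so a record generated at that precision
#' round-trips exactly.
#'
#' @param record a [qc_record()].
#' @param path destination file; when `NULL` the lines are returned.
#' @return the log lines (invisibly when written to `path`).
#' @export
write_qc_log <- function(record, path = NULL) {
  stopifnot(inherits(record, "qc_record"))
  out <- character(0)
  if (!is.null(record$charge) && !is.null(record$multiplicity)) {
    out <- c(out, sprintf(" Charge = %2d Multiplicity = %d",
                          record$charge, record$multiplicity))
  }
  if (!is.null(record$dielectric)) {
    out <- c(out, sprintf(" Eps= %12.6f", record$dielectric))
  }
  out <- c(out, sprintf(" SCF Done:  E(RB3LYP) =  %.9f     A.U. after   11 cycles",
                        record$final_energy_au))
  fr <- record$frequencies_cm1
  if (length(fr) > 0) {
    for (i in seq(1, length(fr), by = 3)) {
      chunk <- fr[i:min(i + 2, length(fr))]
      out <- c(out, paste0(" Frequencies --  ",
                           paste(sprintf("%12.4f", chunk), collapse = "  ")))
    }
  }
  if (!is.null(record$rotational_constants_ghz)) {
    out <- c(out, paste0(" Rotational constants (GHZ):",
                         paste(sprintf("%16.7f",
                                       record$rotational_constants_ghz),
                               collapse = "")))
  }
  if (!is.null(record$mass_amu)) {
    out <- c(out, sprintf(" Molecular mass: %13.5f amu.", record$mass_amu))
  }
  if (!is.null(record$symmetry_number)) {
    out <- c(out, sprintf(" Rotational symmetry number %2d.",
                          record$symmetry_number))
  }
  tc <- record$thermal_corrections
  if (!is.null(tc)) {
    fmt <- function(label, v) sprintf(" %s %.6f", label, v)
    if (!is.null(tc$zpe)) out <- c(out, fmt(
      "Zero-point correction=                          ", tc$zpe))
    if (!is.null(tc$energy)) out <- c(out, fmt(
      "Thermal correction to Energy=                   ", tc$energy))
    if (!is.null(tc$enthalpy)) out <- c(out, fmt(
      "Thermal correction to Enthalpy=                 ", tc$enthalpy))
    if (!is.null(tc$gibbs)) out <- c(out, fmt(
      "Thermal correction to Gibbs Free Energy=        ", tc$gibbs))
  }
  out <- c(out, " Normal termination of Gaussian-style synthetic log.")
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Random qc_record at the log dialect's native precision
#'
#' Draws a synthetic molecule record whose numeric fields sit exactly on the
#' precision grid [write_qc_log()] prints (energies 9 decimals, frequencies
#' 4, thermal corrections 6), so that write/parse round trips are exact.
#' Roughly one in three records carries an imaginary mode (a transition
#' state); optional sections are included at random.
#'
#' @param seed integer seed.
#' @return a [qc_record()].
#' @export
random_qc_record <- function(seed) {
  set.seed(seed)
  n_modes <- sample(0:25, 1)
  freqs <- round(stats::runif(n_modes, 20, 3800), 4)
  if (n_modes > 0 && stats::runif(1) < 1 / 3) {
    freqs[1] <- -round(stats::runif(1, 100, 1500), 4)
  }
  has <- function(p) stats::runif(1) < p
  tc <- NULL
  if (has(0.7)) {
    zpe <- round(stats::runif(1, 0, 0.3), 6)
    tc <- list(zpe = zpe,
               energy = round(zpe + stats::runif(1, 0, 0.02), 6),
               enthalpy = round(zpe + stats::runif(1, 0, 0.03), 6),
               gibbs = round(zpe - stats::runif(1, 0, 0.05), 6))
  }
  qc_record(
    final_energy_au = round(stats::runif(1, -7000, -50), 9),
    frequencies_cm1 = freqs,
    thermal_corrections = tc,
    dielectric = if (has(0.5)) round(sample(c(4, 80), 1) + 0, 6) else NULL,
    mass_amu = if (has(0.7)) round(stats::runif(1, 10, 600), 5) else NULL,
    rotational_constants_ghz =
      if (has(0.6)) round(sort(stats::runif(3, 0.3, 20), decreasing = TRUE), 7)
      else NULL,
    symmetry_number = if (has(0.6)) sample(1:3, 1) else NULL,
    # the dialect prints charge and multiplicity on one line: both or neither
    charge = if (has_cm <- has(0.8)) sample(-2:1, 1) else NULL,
    multiplicity = if (has_cm) sample(1:2, 1) else NULL
  )
}

#' Paths to the packaged transcribed fixtures
#'
#' The package ships plain-text transcriptions of the published reference
#' tables: `table1_models` (cluster-model metadata), `table2_qm3_absolute`
#' (QM3 absolute electronic energies, hartree), `table2_relative_all_models`
#' (relative energies for QM1/QM2/QM3, CPCM and gas phase),
#' `table3_barriers` (per-functional step barriers and selectivity),
#' `table5_bras` (dissociation-corrected overall barriers/reaction
#' energies) and `table4_balanced` (balanced-equation overall values; used
#' for report formatting only, since the auxiliary energies behind it are
#' not published).
#'
#' @return named character vector of file paths.
#' @export
packaged_fixtures <- function() {
  names <- c("table1_models", "table2_qm3_absolute",
             "table2_relative_all_models", "table3_barriers",
             "table4_balanced", "table5_bras")
  files <- paste0(names, ".tsv")
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "qmstitch", mustWork = TRUE),
    character(1))
  stats::setNames(paths, names)
}
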