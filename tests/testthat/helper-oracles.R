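# Independent oracles used by the property tests. These deliberately do not
# share code paths (or derived constants) with the package: the RRHO oracle
# assembles everything per mode / per degree of freedom from Helmholtz and
# internal energies and takes S = (U - A)/T, where the package combines
# closed-form entropy expressions directly.

oracle_rrho <- function(freqs_cm1, mass_amu, rot_ghz, sigma, T, P_atm,
                        multiplicity = 1) {
  h <- 6.62607015e-34; c_cm <- 2.99792458e10; kB <- 1.380649e-23
  NAv <- 6.02214076e23; Rj <- kB * NAv
  J2kcal <- 1 / (4.184 * 1000)           # per-mole J -> kcal
  kcal <- function(x) x * J2kcal

  freqs <- freqs_cm1[freqs_cm1 > 0]
  # vibrational: per-mode loop, U and A including the half-quantum
  U_vib <- 0; A_vib <- 0; zpe <- 0
  for (nu in freqs) {
    theta <- h * c_cm * nu / kB
    zpe <- zpe + 0.5 * Rj * theta
    U_vib <- U_vib + Rj * theta * (0.5 + 1 / (exp(theta / T) - 1))
    A_vib <- A_vib + 0.5 * Rj * theta + Rj * T * log(1 - exp(-theta / T))
  }
  S_vib <- (U_vib - A_vib) / T

  # rotational (nonlinear top)
  th <- h * rot_ghz * 1e9 / kB
  q_rot <- sqrt(pi) / sigma * sqrt(T^3 / (th[1] * th[2] * th[3]))
  U_rot <- 1.5 * Rj * T
  A_rot <- -Rj * T * log(q_rot)
  S_rot <- (U_rot - A_rot) / T

  # translational
  m <- mass_amu * 1.66053906660e-27
  P <- P_atm * 101325
  q_tr <- (2 * pi * m * kB * T / h^2)^1.5 * kB * T / P
  U_tr <- 1.5 * Rj * T
  A_tr <- -Rj * T * (log(q_tr) + 1)      # indistinguishability via Stirling
  S_tr <- (U_tr - A_tr) / T

  S_el <- Rj * log(multiplicity)

  U <- U_vib + U_rot + U_tr
  S <- S_vib + S_rot + S_tr + S_el
  H <- U + Rj * T
  G <- H - T * S
  list(zpe = kcal(zpe),
       thermal_enthalpy = kcal(H),
       entropy_cal = S / 4.184,
       gibbs_correction = kcal(G))
}

random_molecule <- function(seed) {
  set.seed(seed)
  list(freqs = stats::runif(sample(3:40, 1), 40, 3600),
       mass = stats::runif(1, 16, 500),
       rot = sort(stats::runif(3, 0.4, 15), decreasing = TRUE),
       sigma = sample(1:3, 1),
       T = stats::runif(1, 200, 400),
       P = stats::runif(1, 0.5, 2),
       mult = sample(1:2, 1))
}

# elementary step built directly from barrier/reaction-energy numbers
step_from_barriers <- function(name, reactant, ts, product,
                               barrier, reaction = NA_real_) {
  rel <- stats::setNames(c(0, barrier, reaction), c(reactant, ts, product))
  elementary_step(name, rel, reactant, ts, product)
}

fixture_steps_qm3 <- function() {
  tab <- load_species_table(packaged_fixtures()[["table2_qm3_absolute"]])
  list(
    fructosylation = relative_energies(tab, "RC", step = "fructosylation"),
    hydrolysis = relative_energies(tab, "IM2", step = "hydrolysis"),
    transfructosylation = relative_energies(tab, "IM3",
                                            step = "transfructosylation")
  )
}
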