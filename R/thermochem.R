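# Rigid-rotor harmonic-oscillator (RRHO) ideal-gas thermochemistry and the
# two-dielectric dissociation free-energy cycle.

#' RRHO thermal corrections from harmonic frequencies
#'
#' Standard ideal-gas rigid-rotor harmonic-oscillator thermochemistry.
#' Zero-point energy is the sum of half-quanta over all real modes;
#' vibrational, rotational and translational partition-function
#' contributions are combined into the thermal enthalpy correction
#' (including the pV = RT term) and the total entropy. The Gibbs correction
#' satisfies `gibbs = enthalpy - T * entropy` identically.
#'
#' Imaginary modes (negative wavenumbers) are excluded from the vibrational
#' sums with a warning in the default lenient mode (transition-state records
#' carry one); `strict = TRUE` makes them an error. An exactly zero
#' wavenumber is always an error (the harmonic oscillator is undefined).
#'
#' @param frequencies_cm1 harmonic wavenumbers, cm^-1; negative values are
#'   imaginary modes. An empty vector is the single-atom limit (no
#'   vibrational contribution).
#' @param mass_amu molecular mass in amu; `NULL` omits the translational
#'   contribution (vibration-only analysis).
#' @param rotational_constants_ghz rotational constants in GHz: length 3 for
#'   a nonlinear top, length 1 for a linear molecule, `NULL` for an atom.
#' @param symmetry_number external rotational symmetry number.
#' @param temperature temperature, K (default 298.15).
#' @param pressure pressure, atm (default 1).
#' @param scale_factor multiplicative frequency scaling (default 1.0).
#' @param multiplicity electronic spin multiplicity (entropy `R ln g`).
#' @param strict if `TRUE`, any imaginary mode is an error.
#' @param low_freq_cutoff optional floor (cm^-1) applied to real modes before
#'   the vibrational sums; default 0 (off).
#' @return object of class `thermo_corrections` with fields `zpe`,
#'   `thermal_enthalpy`, `gibbs_correction` (kcal/mol), `entropy`
#'   (cal/(mol K)), the per-degree-of-freedom components, `temperature`
#'   and `pressure`.
#' @export
#' @examples
#' rrho_corrections(1000)$zpe # ~1.4296 kcal/mol
rrho_corrections <- function(frequencies_cm1,
                             mass_amu = NULL,
                             rotational_constants_ghz = NULL,
                             symmetry_number = 1,
                             temperature = 298.15,
                             pressure = 1,
                             scale_factor = 1,
                             multiplicity = 1,
                             strict = FALSE,
                             low_freq_cutoff = 0) {
  stopifnot(temperature > 0, pressure > 0, scale_factor > 0)
  nu <- as.numeric(frequencies_cm1)
  if (any(nu == 0)) {
    stop("zero wavenumber supplied: RRHO is undefined for a zero-frequency ",
         "mode", call. = FALSE)
  }
  imag <- nu < 0
  if (any(imag)) {
    if (strict) {
      stop("imaginary mode(s) present in strict mode: ",
           paste(sprintf("%.1fi", -nu[imag]), collapse = ", "), call. = FALSE)
    }
    warning(sum(imag), " imaginary mode(s) excluded from vibrational sums",
            call. = FALSE)
    nu <- nu[!imag]
  }
  nu <- nu * scale_factor
  if (low_freq_cutoff > 0) nu <- pmax(nu, low_freq_cutoff)

  T <- temperature
  R_kcal <- .const$R_kcal
  R_cal <- .const$R_cal

  # vibrational: theta_i = h c nu / kB
  theta <- .const$cm1_K * nu
  zpe <- sum(0.5 * .const$cm1_kcal * nu)
  x <- theta / T
  e_vib <- R_kcal * sum(theta / expm1(x))                      # thermal part
  s_vib <- R_cal * sum(x / expm1(x) - log1p(-exp(-x)))
  if (length(nu) == 0) {
    e_vib <- 0; s_vib <- 0; zpe <- 0
  }

  # rotational
  B <- rotational_constants_ghz
  if (is.null(B)) {
    e_rot <- 0; s_rot <- 0
  } else if (length(B) == 1) {
    theta_r <- .const$h * B * 1e9 / .const$kB
    q_rot <- T / (symmetry_number * theta_r)
    e_rot <- R_kcal * T
    s_rot <- R_cal * (log(q_rot) + 1)
  } else if (length(B) == 3) {
    theta_r <- .const$h * B * 1e9 / .const$kB
    q_rot <- sqrt(pi) / symmetry_number * sqrt(T^3 / prod(theta_r))
    e_rot <- 1.5 * R_kcal * T
    s_rot <- R_cal * (log(q_rot) + 1.5)
  } else {
    stop("rotational_constants_ghz must have length 1 (linear), 3 ",
         "(nonlinear) or be NULL (atom)", call. = FALSE)
  }

  # translational (Sackur-Tetrode at the given pressure)
  if (is.null(mass_amu)) {
    e_trans <- 0; s_trans <- 0; pv <- 0
  } else {
    m <- mass_amu * .const$amu_kg
    P <- pressure * .const$atm_pa
    q_trans <- (2 * pi * m * .const$kB * T / .const$h^2)^1.5 *
      (.const$kB * T / P)
    e_trans <- 1.5 * R_kcal * T
    s_trans <- R_cal * (log(q_trans) + 2.5)
    pv <- R_kcal * T
  }

  s_elec <- R_cal * log(multiplicity)

  entropy <- s_vib + s_rot + s_trans + s_elec                  # cal/(mol K)
  thermal_enthalpy <- zpe + e_vib + e_rot + e_trans + pv       # kcal/mol
  gibbs_correction <- thermal_enthalpy - T * entropy / 1000

  structure(list(
    zpe = zpe,
    thermal_enthalpy = thermal_enthalpy,
    entropy = entropy,
    gibbs_correction = gibbs_correction,
    temperature = T,
    pressure = pressure,
    components = list(
      e_vib_thermal = e_vib, e_rot = e_rot, e_trans = e_trans, pv = pv,
      s_vib = s_vib, s_rot = s_rot, s_trans = s_trans, s_elec = s_elec),
    n_modes = length(nu)
  ), class = "thermo_corrections")
}

#' @export
print.thermo_corrections <- function(x, ...) {
  cat("<thermo_corrections> RRHO at", x$temperature, "K,", x$pressure, "atm\n")
  cat(sprintf("  ZPE               %10.4f kcal/mol\n", x$zpe))
  cat(sprintf("  H correction      %10.4f kcal/mol\n", x$thermal_enthalpy))
  cat(sprintf("  S                 %10.4f cal/(mol K)\n", x$entropy))
  cat(sprintf("  G correction      %10.4f kcal/mol\n", x$gibbs_correction))
  invisible(x)
}

#' Absolute Gibbs energy on the kcal/mol scale
#'
#' Assembles `G = E_elec (converted to kcal/mol) + Gibbs correction`, the
#' quantity entering the dissociation free-energy cycle.
#'
#' @param electronic_energy_au electronic energy, hartree.
#' @param corrections a [rrho_corrections()] result (or any list with a
#'   `gibbs_correction` field in kcal/mol).
#' @return Gibbs energy, kcal/mol (absolute scale).
#' @export
gibbs_energy <- function(electronic_energy_au, corrections) {
  hartree_to_kcalmol(electronic_energy_au) + corrections$gibbs_correction
}

#' Dissociation free energy from two dielectric environments
#'
#' The dissociation free energy of a leaving molecule (glucose in the
#' glycosidase cycle) is estimated as the difference between its Gibbs
#' energy in a low-dielectric, protein-like continuum (eps ~ 4) and in a
#' high-dielectric, water-like continuum (eps ~ 80):
#' `dG_diss = G(eps_low) - G(eps_high)`. The sign is not forced: a molecule
#' better stabilised in water gives a positive correction, which is applied
#' as an increment at the junction when stitching half-reactions.
#'
#' @param g_low_eps Gibbs energy in the low-dielectric environment, kcal/mol.
#' @param g_high_eps Gibbs energy in the high-dielectric environment, kcal/mol.
#' @param eps_low,eps_high the relative permittivities; `eps_low < eps_high`
#'   is required by convention.
#' @return object of class `dissociation_correction` with field
#'   `delta_g_diss`.
#' @export
#' @examples
#' dissociation_free_energy(-100.0, -103.1, 4, 80)$delta_g_diss # 3.1
dissociation_free_energy <- function(g_low_eps, g_high_eps,
                                     eps_low = 4, eps_high = 80) {
  if (eps_low >= eps_high) {
    stop("convention requires eps_low < eps_high (protein-like vs ",
         "water-like environment)", call. = FALSE)
  }
  structure(list(
    g_low_eps = g_low_eps,
    g_high_eps = g_high_eps,
    eps_low = eps_low,
    eps_high = eps_high,
    delta_g_diss = g_low_eps - g_high_eps
  ), class = "dissociation_correction")
}

#' @export
print.dissociation_correction <- function(x, ...) {
  cat(sprintf(
    "<dissociation_correction> dG_diss = %.2f kcal/mol (eps %g -> %g)\n",
    x$delta_g_diss, x$eps_low, x$eps_high))
  invisible(x)
}
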