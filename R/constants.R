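# Physical constants (CODATA 2018 exact SI values where defined).
# All thermochemistry below is derived from these; the hartree -> kcal/mol
# factor is fixed at 627.5095, the value conventional in the cluster-model
# enzyme-energetics literature.

.const <- list(
  hartree_kcal = 627.5095,            # kcal/mol per hartree
  h            = 6.62607015e-34,      # J s
  c_cm         = 2.99792458e10,       # cm/s
  kB           = 1.380649e-23,        # J/K
  NA_mol       = 6.02214076e23,       # 1/mol
  amu_kg       = 1.66053906660e-27,   # kg per amu
  atm_pa       = 101325,              # Pa per atm
  cal_J        = 4.184                # J per thermochemical calorie
)
# derived
.const$R_J        <- .const$kB * .const$NA_mol              # J/(mol K)
.const$R_kcal     <- .const$R_J / (.const$cal_J * 1000)     # kcal/(mol K)
.const$R_cal      <- .const$R_J / .const$cal_J              # cal/(mol K)
.const$cm1_kcal   <- .const$h * .const$c_cm * .const$NA_mol /
  (.const$cal_J * 1000)                                     # kcal/mol per cm^-1
.const$cm1_K      <- .const$h * .const$c_cm / .const$kB     # K per cm^-1

#' Convert an electronic energy difference from hartree to kcal/mol
#'
#' Uses the conversion factor 627.5095 kcal/mol per hartree. The sign is
#' preserved exactly; a zero difference maps to exactly zero.
#'
#' @param delta_au numeric vector of energy differences in hartree.
#' @return numeric vector in kcal/mol.
#' @export
#' @examples
#' hartree_to_kcalmol(0.029568) # ~18.55 kcal/mol
hartree_to_kcalmol <- function(delta_au) {
  if (!is.numeric(delta_au)) {
    stop("`delta_au` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(delta_au))) {
    stop("non-finite energy difference supplied to hartree_to_kcalmol()",
         call. = FALSE)
  }
  delta_au * .const$hartree_kcal
}

#' Round for display: half away from zero, one decimal by default
#'
#' Report-time rounding used for all rendered tables. Internal arithmetic is
#' always carried at full precision; this is applied exactly once at render.
#'
#' @param x numeric vector.
#' @param digits number of decimals (default 1).
#' @return rounded numeric vector.
#' @export
display_round <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
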