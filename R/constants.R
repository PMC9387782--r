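# Physical constants in the package unit system:
# length A, energy kcal/mol, mass amu, time ps, charge e, temperature K.

# 1 amu A^2 / ps^2 = 1.66053906660e-23 J * 6.02214076e23 / mol = 10.0 J/mol
# (the product N_A * 1 amu is 1e-3 kg/mol by definition of the mole),
# hence 1 kcal/mol = 4184 J/mol = 418.4 amu A^2 / ps^2.
KCAL_TO_AMU_A2_PS2 <- 418.4

# Boltzmann constant, kcal/(mol K)
KB_KCAL <- 0.0019872041

# hbar in amu A^2 / ps (1.054571817e-34 J s / 1.66053906660e-35 J s per unit)
HBAR_AMU_A2_PS <- 1.054571817e-34 / (1.66053906660e-27 * 1e-20 / 1e-12)

# Coulomb constant, kcal A / (mol e^2)
COULOMB_K <- 332.0636

#' Thermodynamic bookkeeping parameters
#'
#' Bundles the temperature and the physical constants used by the entropy and
#' interaction-energy modules, expressed in the package unit system
#' (angstrom, kcal/mol, amu, ps, elementary charge).
#'
#' @param temperature Temperature in kelvin. Default 300 K, the thermostat
#'   temperature the simulations these analyses target are coupled to.
#' @return An object of class `thermo_params`: a list with `temperature`,
#'   `k_B` (kcal/(mol K)), `hbar` (amu A^2/ps), `coulomb_k` (kcal A/(mol e^2))
#'   and `kcal_to_internal` (conversion from kcal/mol to amu A^2/ps^2).
#' @export
#' @examples
#' th <- thermo_params()
#' th$k_B * th$temperature  # thermal energy at 300 K, kcal/mol
thermo_params <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1, temperature > 0)
  structure(
    list(
      temperature = temperature,
      k_B = KB_KCAL,
      hbar = HBAR_AMU_A2_PS,
      coulomb_k = COULOMB_K,
      kcal_to_internal = KCAL_TO_AMU_A2_PS2
    ),
    class = "thermo_params"
  )
}
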