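#' Physical constants used throughout the package
#'
#' Working units are Angstrom, kcal/mol and picosecond. The Boltzmann
#' constant is 0.0019872 kcal/mol/K, so at the default temperature of 300 K
#' the thermal energy is 0.5962 kcal/mol.
#'
#' @format A named list with components:
#' \describe{
#'   \item{k_B}{Boltzmann constant, kcal/mol/K.}
#'   \item{kcal_per_mol_per_eV}{Energy of one electron through one volt,
#'     kcal/mol per eV (23.0605).}
#'   \item{nN_per_kcal_mol_A}{Force conversion: 1 kcal/mol/A = 0.06948 nN.}
#' }
#' @export
constants <- list(
  k_B = 0.0019872,
  kcal_per_mol_per_eV = 23.0605,
  nN_per_kcal_mol_A = 0.06948
)

#' Thermal energy k_B T
#'
#' @param temperature Temperature in Kelvin.
#' @param multiple Integer multiple of k_B T (default 1); e.g. `multiple = 2`
#'   gives the ~1.2 kcal/mol lateral-bias scale at 300 K.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' thermal_energy(300, 2) # ~1.2 kcal/mol
thermal_energy <- function(temperature, multiple = 1) {
  stopifnot(is.numeric(temperature), all(temperature >= 0))
  multiple * constants$k_B * temperature
}

#' Convert a membrane potential to an energy per ion group
#'
#' The energy gained by `n_charges` elementary charges falling through a
#' membrane potential `V`: E = n |e| V, expressed in kcal/mol. Sign is
#' preserved, so -100 mV across three charges gives -6.9 kcal/mol.
#'
#' @param V Membrane potential in mV (signed).
#' @param n_charges Number of elementary charges moved together (>= 1).
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' potential_to_energy(-100, 3) # -6.92
potential_to_energy <- function(V, n_charges) {
  if (any(n_charges < 1)) stop("`n_charges` must be >= 1")
  n_charges * (V / 1000) * constants$kcal_per_mol_per_eV
}

#' Convert an energy to the equivalent membrane potential
#'
#' Exact inverse of [potential_to_energy()]: V = E / (n |e|) in mV. Breaking
#' a multi-ion block costing 5-10 kcal/mol across three charges corresponds
#' to membrane potentials of magnitude 72-145 mV.
#'
#' @param E Energy in kcal/mol.
#' @param n_charges Number of elementary charges (>= 1).
#' @return Potential in mV.
#' @export
#' @examples
#' energy_to_potential(10, 3) # 144.6 mV
energy_to_potential <- function(E, n_charges) {
  if (any(n_charges < 1)) stop("`n_charges` must be >= 1")
  E / (n_charges * constants$kcal_per_mol_per_eV) * 1000
}

#' Convert a force from kcal/mol/A to nanonewtons
#'
#' @param F Force in kcal/mol/A.
#' @return Force in nN (1 kcal/mol/A = 0.06948 nN).
#' @export
#' @examples
#' force_to_nN(14) # ~1.0 nN, the scale of inter-ion repulsion in a block
force_to_nN <- function(F) {
  F * constants$nN_per_kcal_mol_A
}
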