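# Physical constants used throughout. Energies are carried in eV everywhere in
# the interchange format; atomic units appear only inside the transition-dipole
# conversion.
HC_EV_NM <- 1239.84198   # hc, eV * nm
HARTREE_EV <- 27.211386  # 1 hartree in eV

#' Convert excitation energy to wavelength
#'
#' Applies the standard relation lambda = hc / E with hc = 1239.84198 eV nm,
#' the conversion used for all wavelength axes in this package.
#'
#' @param energy_ev Numeric vector of energies in eV; all values must be > 0.
#' @return Wavelengths in nm.
#' @seealso [nm_to_ev()] for the inverse.
#' @examples
#' ev_to_nm(2.753)   # ~450.4 nm, the weak n-pi* vertical excitation of azobenzene
#' @export
ev_to_nm <- function(energy_ev) {
  if (!is.numeric(energy_ev) || any(!is.finite(energy_ev)) || any(energy_ev <= 0))
    stop("energy_ev must be finite and > 0")
  HC_EV_NM / energy_ev
}

#' Convert wavelength to excitation energy
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm; all values > 0.
#' @return Energies in eV.
#' @export
nm_to_ev <- function(wavelength_nm) {
  if (!is.numeric(wavelength_nm) || any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0))
    stop("wavelength_nm must be finite and > 0")
  HC_EV_NM / wavelength_nm
}

#' Transition probability weight of one excitation
#'
#' In the ensemble construction of a band shape every excitation contributes
#' f / dE to the histogram of excitation energies, because the transition
#' probability is proportional to the oscillator strength divided by the
#' excitation energy. This is the weight that replaces the count of one in a
#' regular frequency histogram.
#'
#' @param delta_e_ev Excitation energy in eV, > 0.
#' @param osc_strength Dimensionless oscillator strength, >= 0.
#' @return The weight f / dE (vectorised).
#' @export
transition_weight <- function(delta_e_ev, osc_strength) {
  if (any(!is.finite(delta_e_ev)) || any(delta_e_ev <= 0))
    stop("delta_e_ev must be finite and > 0")
  if (any(!is.finite(osc_strength)) || any(osc_strength < 0))
    stop("osc_strength must be finite and >= 0")
  osc_strength / delta_e_ev
}

#' Squared transition dipole moment from oscillator strength
#'
#' Inverts the oscillator-strength relation f = (2/3) dE |mu|^2 (atomic units)
#' to recover |mu_if|^2 from an excitation energy and oscillator strength.
#'
#' @param delta_e_ev Excitation energy in eV, > 0.
#' @param osc_strength Oscillator strength, >= 0.
#' @return |mu_if|^2 in atomic units (e^2 a0^2).
#' @export
dipole_sq_from_f <- function(delta_e_ev, osc_strength) {
  if (any(!is.finite(delta_e_ev)) || any(delta_e_ev <= 0))
    stop("delta_e_ev must be finite and > 0")
  if (any(!is.finite(osc_strength)) || any(osc_strength < 0))
    stop("osc_strength must be finite and >= 0")
  3 * osc_strength / (2 * (delta_e_ev / HARTREE_EV))
}
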