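#' Physical constants used by mosscalib
#'
#' CODATA-2018 values, SI units. `E_gamma_57Fe_keV` is the energy of the
#' 14.4 keV Mossbauer transition of 57Fe used to convert energy shifts into
#' Doppler velocities.
#'
#' @format A named list:
#' \describe{
#'   \item{hartree_J}{Hartree energy, J.}
#'   \item{bohr_m}{Bohr radius, m.}
#'   \item{c_m_s}{Speed of light in vacuum, m/s.}
#'   \item{e_C}{Elementary charge, C.}
#'   \item{barn_m2}{1 barn in m^2.}
#'   \item{angstrom_bohr}{Bohr radii per Angstrom.}
#'   \item{E_gamma_57Fe_keV}{57Fe Mossbauer gamma energy, keV.}
#' }
#' @export
moss_constants <- list(
  hartree_J        = 4.3597447222071e-18,
  bohr_m           = 0.529177210903e-10,
  c_m_s            = 299792458,
  e_C              = 1.602176634e-19,
  barn_m2          = 1e-28,
  angstrom_bohr    = 1 / 0.529177210903,
  E_gamma_57Fe_keV = 14.4125
)
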