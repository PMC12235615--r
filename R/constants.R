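# Physical constants (CODATA 2018) used for unit handling.  Everything the
# engine computes internally is expressed in wavenumbers (cm^-1) for energies
# and force constants, debye for dipoles, and dimensionless normal
# coordinates q for all derivatives.

.const <- list(
  h      = 6.62607015e-34,    # Planck constant, J s (exact)
  hbar   = 6.62607015e-34 / (2 * pi),
  c      = 2.99792458e8,      # speed of light, m/s (exact)
  c_cm   = 2.99792458e10,     # cm/s
  NA_    = 6.02214076e23,     # Avogadro constant, 1/mol (exact)
  eps0   = 8.8541878128e-12,  # vacuum permittivity, F/m
  debye  = 3.33564095198e-30, # C m
  u      = 1.66053906660e-27, # unified atomic mass unit, kg
  ang    = 1e-10              # m
)

#' Scale factor between mass-weighted and dimensionless normal coordinates
#'
#' The dimensionless (reduced) normal coordinate is
#' \eqn{q_i = Q_i \sqrt{2\pi c \tilde\omega_i/\hbar}}, where \eqn{Q_i} is the
#' mass-weighted normal coordinate.  This returns the factor
#' \eqn{\sqrt{2\pi c \tilde\omega/\hbar}} expressed per \eqn{\sqrt{u}\,\AA},
#' i.e. the value of \eqn{q} reached by a displacement of 1 \eqn{\sqrt{u}\,\AA}
#' along the mass-weighted coordinate of a mode of wavenumber \code{omega}.
#'
#' @param omega harmonic wavenumber(s), cm^-1.
#' @return numeric scale factor(s), dimensionless q per sqrt(u) Angstrom.
#' @examples
#' q_scale(1000)   # ~ 5.446
#' @export
q_scale <- function(omega) {
  stopifnot(all(omega > 0))
  sqrt(2 * pi * .const$c_cm * omega * .const$u * .const$ang^2 / .const$hbar)
}

# Molar absorption prefactor: integrated intensity in km/mol of a transition
# at nu (cm^-1) with squared transition moment |mu|^2 (debye^2) is
#   I = ir_prefactor() * nu * |mu|^2
# assembled as 2 pi^2 N_A / (3 h c eps0), converted to km/mol per cm^-1 D^2.
# In the double-harmonic limit this reproduces the standard convention
# (42.2561 km/mol for dmu/dQ = 1 D A^-1 u^-1/2).
ir_prefactor <- function() {
  si <- 2 * pi^2 * .const$NA_ / (3 * .const$h * .const$c * .const$eps0)
  si * 100 * .const$debye^2 / 1000
}
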