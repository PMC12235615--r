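# Synthetic model systems with known structure.  Each generator returns an
# "AFF triple": list(basis, ff, dip) ready for the perturbative engine, the
# VCI oracle and the AFF writer.  The normal-mode part is abstract (unit
# masses, identity-like mode vectors): the anharmonic machinery only consumes
# omega and the reduced-coordinate tensors.

toy_basis <- function(omega, level_tag = "toy") {
  M <- length(omega)
  n_atoms <- ceiling((M + 6) / 3)
  L <- diag(3 * n_atoms)[, seq_len(M), drop = FALSE]
  normal_mode_basis(masses = rep(1, n_atoms),
                    geometry = matrix(0, n_atoms, 3),
                    L = L, omega = omega, level_tag = level_tag)
}

#' One-mode Morse oscillator as a quartic force field
#'
#' Expands the Morse potential \eqn{V(q) = D(1 - e^{-\alpha q})^2} with
#' \eqn{\alpha = \sqrt{\omega/2D}} (so that \eqn{V''(0) = \omega}) to fourth
#' order in the dimensionless coordinate: \eqn{f_3 = -6D\alpha^3},
#' \eqn{f_4 = 14D\alpha^4}.  VPT2 on this truncation reproduces the exact
#' Morse anharmonicity \eqn{\omega x_e = \omega^2/(4D)}, so the exact ladder
#' \eqn{E_n - E_0 = \omega n - \omega x_e (n^2 + n)} is the analytic target.
#'
#' @param omega_cm harmonic wavenumber, cm^-1.
#' @param D_cm dissociation energy, cm^-1 (must exceed \code{omega_cm}).
#' @param dipole_linear,dipole_quadratic dipole derivatives along the mode
#'   (x component), debye per unit q.
#' @return list with elements \code{basis}, \code{ff}, \code{dip}.
#' @examples
#' toy <- morse_ff(1600, 64000)   # omega*x_e = 10 cm^-1
#' @export
morse_ff <- function(omega_cm, D_cm, dipole_linear = 0.3, dipole_quadratic = 0) {
  if (D_cm <= omega_cm) stop("nonphysical Morse parameters: need D > omega")
  alpha <- sqrt(omega_cm / (2 * D_cm))
  f3 <- -6 * D_cm * alpha^3
  f4 <- 14 * D_cm * alpha^4
  cubic <- array(f3, dim = c(1, 1, 1))
  quartic <- array(f4, dim = c(1, 1, 1))
  d1 <- matrix(c(dipole_linear, 0, 0), 1, 3)
  d2 <- array(0, dim = c(1, 1, 3)); d2[1, 1, 1] <- dipole_quadratic
  list(basis = toy_basis(omega_cm, "toy-morse"),
       ff = anharmonic_ff(omega_cm, cubic, quartic, level_tag = "toy-morse"),
       dip = dipole_surface(d1 = d1, d2 = d2))
}

#' Two-mode Fermi-resonance model
#'
#' A bright fundamental \eqn{\omega_1 \approx 2\omega_2} coupled to the dark
#' overtone of mode 2 through the single cubic constant \eqn{f_{122}}, the
#' textbook Fermi pair.  The detuning \eqn{\Delta = \omega_1 - 2\omega_2} and
#' the coupling \eqn{W = f_{122}/4} can be placed anywhere in the
#' \eqn{(\Delta, W)} plane.
#'
#' @param omega1 wavenumber of the bright mode, cm^-1.
#' @param omega2 wavenumber of the dark mode, cm^-1 (default places
#'   \eqn{\Delta = } \code{delta}).
#' @param f122 Fermi cubic constant, cm^-1.
#' @param delta detuning used when \code{omega2} is NULL.
#' @param extra_quartics optional named list with entries \code{f1111},
#'   \code{f2222}, \code{f1122} (cm^-1).
#' @param dipole_d1 length-2 vector: x-component dipole first derivative for
#'   each mode, debye per unit q.
#' @param dipole_d222 x-component second derivative for mode 2
#'   (\eqn{\partial^2\mu_x/\partial q_2^2}), giving the overtone a direct
#'   electrical route.
#' @return list with elements \code{basis}, \code{ff}, \code{dip}.
#' @examples
#' toy <- coupled_fermi_ff(delta = 0, f122 = 40)   # exact degeneracy
#' @export
coupled_fermi_ff <- function(omega1 = 1600, omega2 = NULL, f122 = 40,
                             delta = 0, extra_quartics = list(),
                             dipole_d1 = c(0.3, 0.05), dipole_d222 = 0) {
  if (is.null(omega2)) omega2 <- (omega1 - delta) / 2
  omega <- c(omega1, omega2)
  cubic <- array(0, dim = c(2, 2, 2))
  cubic[1, 2, 2] <- cubic[2, 1, 2] <- cubic[2, 2, 1] <- f122
  quartic <- array(0, dim = c(2, 2, 2))
  if (!is.null(extra_quartics$f1111)) quartic[1, 1, 1] <- extra_quartics$f1111
  if (!is.null(extra_quartics$f2222)) quartic[2, 2, 2] <- extra_quartics$f2222
  if (!is.null(extra_quartics$f1122)) {
    quartic[1, 2, 2] <- quartic[2, 1, 1] <- extra_quartics$f1122
  }
  d1 <- cbind(dipole_d1, 0, 0)
  d2 <- array(0, dim = c(2, 2, 3)); d2[2, 2, 1] <- dipole_d222
  list(basis = toy_basis(omega, "toy-fermi"),
       ff = anharmonic_ff(omega, cubic, quartic, level_tag = "toy-fermi"),
       dip = dipole_surface(d1 = d1, d2 = d2))
}

#' Seeded random weakly anharmonic force field
#'
#' Harmonic wavenumbers drawn uniformly from [400, 1800] cm^-1 with a minimum
#' pairwise gap of 150 cm^-1 (so that perturbation-theory validity is not
#' confounded by accidental resonances), unless \code{resonant = TRUE}, which
#' forces \eqn{\omega_1 \approx \omega_2 + \omega_3} to within 20 cm^-1.
#' Cubic and quartic constants are drawn uniformly with magnitudes bounded by
#' \code{cubic_scale} and \code{quartic_scale}; the defaults keep
#' \eqn{|f_3| \le 0.03\,\min\omega}, small enough for VPT2 validity.
#'
#' @param M number of modes.
#' @param seed integer seed; the same seed always reproduces the same field.
#' @param cubic_scale,quartic_scale absolute magnitude bounds, cm^-1
#'   (defaults 0.03 and 0.003 times the smallest wavenumber drawn).
#' @param dipole_scale magnitude bound for dipole first derivatives, debye
#'   per unit q (second and third derivatives are scaled down by 10 and 100).
#' @param resonant force a Fermi-type near-degeneracy (requires M >= 3).
#' @return list with elements \code{basis}, \code{ff}, \code{dip}.
#' @export
random_ff <- function(M, seed, cubic_scale = NULL, quartic_scale = NULL,
                      dipole_scale = 0.2, resonant = FALSE) {
  stopifnot(M >= 1)
  with_seed(seed, {
    repeat {
      omega <- sort(stats::runif(M, 400, 1800), decreasing = TRUE)
      if (M == 1 || min(abs(diff(omega))) >= 150) break
    }
    if (resonant) {
      if (M < 3) stop("resonant random fields need at least 3 modes")
      omega[1] <- omega[2] + omega[3] + stats::runif(1, -20, 20)
      omega <- sort(omega, decreasing = TRUE)
    }
    if (is.null(cubic_scale)) cubic_scale <- 0.03 * min(omega)
    if (is.null(quartic_scale)) quartic_scale <- 0.003 * min(omega)
    cubic <- array(0, dim = c(M, M, M))
    for (i in seq_len(M)) for (j in i:M) for (k in j:M) {
      v <- stats::runif(1, -cubic_scale, cubic_scale)
      for (p in seq_len(nrow(perms3()))) {
        ix <- c(i, j, k)[perms3()[p, ]]
        cubic[ix[1], ix[2], ix[3]] <- v
      }
    }
    quartic <- array(0, dim = c(M, M, M))
    for (i in seq_len(M)) for (j in seq_len(M)) for (k in j:M) {
      v <- stats::runif(1, -quartic_scale, quartic_scale)
      quartic[i, j, k] <- quartic[i, k, j] <- v
      if (k == j && j != i) quartic[j, i, i] <- v
    }
    d1 <- matrix(stats::runif(3 * M, -dipole_scale, dipole_scale), M, 3)
    d2 <- array(0, dim = c(M, M, 3))
    for (c_ in 1:3) {
      s <- matrix(stats::runif(M * M, -dipole_scale / 10, dipole_scale / 10), M, M)
      d2[, , c_] <- (s + t(s)) / 2
    }
    d3 <- array(stats::runif(M * M * 3, -dipole_scale / 100, dipole_scale / 100),
                dim = c(M, M, 3))
    list(basis = toy_basis(omega, sprintf("toy-random-%d", seed)),
         ff = anharmonic_ff(omega, cubic, quartic,
                            level_tag = sprintf("toy-random-%d", seed)),
         dip = dipole_surface(d1 = d1, d2 = d2, d3 = d3))
  })
}

# evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Exact Morse transition energies
#'
#' \eqn{E_n - E_0 = \omega n - \omega x_e (n^2 + n)} with
#' \eqn{\omega x_e = \omega^2/(4D)}.
#'
#' @param n vector of quanta.
#' @param omega_cm,D_cm Morse parameters, cm^-1.
#' @return transition energies, cm^-1.
#' @export
morse_levels <- function(n, omega_cm, D_cm) {
  wxe <- omega_cm^2 / (4 * D_cm)
  omega_cm * n - wxe * (n^2 + n)
}
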