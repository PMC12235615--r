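#' VPT2 anharmonicity-constant matrix with removable resonant terms
#'
#' Computes the symmetric matrix of second-order anharmonic constants
#' \eqn{\chi_{ij}} (cm^-1) from a quartic force field, with every
#' Fermi-resonant denominator written as an individually removable partial
#' fraction.  With an empty removal set this is plain VPT2; removing the
#' singular fractions of flagged Fermi triples gives the deperturbed
#' constants (DVPT2).
#'
#' Diagonal constants:
#' \deqn{\chi_{ii} = f_{iiii}/16 - \frac{1}{16}\sum_j f_{iij}^2
#'   \left[\frac{2}{\omega_j} + \frac{1}{2(2\omega_i+\omega_j)}
#'   - \frac{1}{2(2\omega_i-\omega_j)}\right]}
#' where the last fraction is the one removed when the triple
#' \eqn{(j,(i,i))} is flagged.  Off-diagonal constants:
#' \deqn{\chi_{ij} = f_{iijj}/4 - \frac{1}{4}\sum_k \frac{f_{iik}f_{jjk}}{\omega_k}
#'  - \frac{1}{8}\sum_k f_{ijk}^2\left[\frac{1}{\omega_i+\omega_j+\omega_k}
#'  + \frac{1}{\omega_j+\omega_k-\omega_i} + \frac{1}{\omega_i+\omega_k-\omega_j}
#'  - \frac{1}{\omega_i+\omega_j-\omega_k}\right]}
#' with the three signed fractions removable for the triples
#' \eqn{(i,(j,k))}, \eqn{(j,(i,k))} and \eqn{(k,(i,j))} respectively.
#'
#' @param ff an \code{\link{anharmonic_ff}}.
#' @param removed Fermi triples to deperturb: integer matrix with columns
#'   (i, j, k), j <= k, meaning \eqn{\omega_i \approx \omega_j + \omega_k};
#'   or NULL for plain VPT2.  Usually taken from accepted resonance edges.
#' @return M x M symmetric matrix of class \code{chi_matrix}; the removal
#'   registry is kept in attribute \code{"removed"}.
#' @examples
#' toy <- morse_ff(1600, 64000)
#' vpt2_chi(toy$ff)   # -10 cm^-1
#' @export
vpt2_chi <- function(ff, removed = NULL) {
  omega <- ff$omega
  M <- length(omega)
  cubic <- ff$cubic
  quartic <- ff$quartic
  flagged <- fermi_flag_set(removed)
  frac <- function(den, i, j, k) {
    # removable fraction 1/den tied to Fermi triple (i,(j,k)); returns 0 when
    # the triple is flagged, errors on an exact unflagged singularity
    if (fermi_is_flagged(flagged, i, j, k)) return(0)
    if (den == 0)
      stop(sprintf(paste0("exact resonance omega_%d = omega_%d + omega_%d with an ",
                          "unflagged denominator; flag the Fermi triple (%d,(%d,%d))"),
                   i, j, k, i, j, k))
    1 / den
  }
  chi <- matrix(0, M, M)
  for (i in seq_len(M)) {
    val <- quartic[i, i, i] / 16
    for (j in seq_len(M)) {
      f <- cubic[i, i, j]
      if (f == 0) next
      s <- 2 / omega[j] + 1 / (2 * (2 * omega[i] + omega[j])) -
        frac(2 * omega[i] - omega[j], j, i, i) / 2
      val <- val - f^2 / 16 * s
    }
    chi[i, i] <- val
  }
  if (M > 1) {
    for (i in seq_len(M - 1)) for (j in (i + 1):M) {
      val <- quartic[i, j, j] / 4
      for (k in seq_len(M)) {
        val <- val - cubic[i, i, k] * cubic[j, j, k] / (4 * omega[k])
        f <- cubic[i, j, k]
        if (f == 0) next
        s <- 1 / (omega[i] + omega[j] + omega[k]) +
          frac(omega[j] + omega[k] - omega[i], i, min(j, k), max(j, k)) +
          frac(omega[i] + omega[k] - omega[j], j, min(i, k), max(i, k)) -
          frac(omega[i] + omega[j] - omega[k], k, min(i, j), max(i, j))
        val <- val - f^2 / 8 * s
      }
      chi[i, j] <- chi[j, i] <- val
    }
  }
  structure(chi, class = c("chi_matrix", "matrix"), removed = removed)
}

fermi_flag_set <- function(removed) {
  if (is.null(removed) || NROW(removed) == 0) return(character(0))
  removed <- matrix(as.integer(removed), ncol = 3)
  apply(removed, 1, function(r) paste(r[1], min(r[2], r[3]), max(r[2], r[3]), sep = "|"))
}

fermi_is_flagged <- function(flagged, i, j, k) {
  length(flagged) > 0 && paste(i, min(j, k), max(j, k), sep = "|") %in% flagged
}

#' VPT2 transition energy of a vibrational state
#'
#' Evaluates \eqn{E(n) - E(0)} from the spectroscopic expansion
#' \eqn{E(n) = \sum_i \omega_i (n_i + 1/2) + \sum_{i \le j} \chi_{ij}
#' (n_i + 1/2)(n_j + 1/2)}.  For a fundamental this reduces to
#' \eqn{\nu_i = \omega_i + 2\chi_{ii} + \frac{1}{2}\sum_{j \ne i}\chi_{ij}},
#' for an overtone \eqn{2\omega_i + 6\chi_{ii} + \sum_{j\ne i}\chi_{ij}}.
#'
#' @param state integer quanta vector (or \code{vib_state}).
#' @param omega harmonic wavenumbers, cm^-1.
#' @param chi matrix from \code{\link{vpt2_chi}}.
#' @return transition energy, cm^-1.
#' @export
vpt2_transition_energy <- function(state, omega, chi) {
  n <- as.numeric(state)
  stopifnot(length(n) == length(omega))
  x <- n + 0.5
  e <- sum(n * omega)
  # sum_{i<=j} chi_ij [(n_i+1/2)(n_j+1/2) - 1/4]
  P <- outer(x, x) - 0.25
  e + sum(chi[upper.tri(chi)] * P[upper.tri(P)]) + sum(diag(chi) * (x^2 - 0.25))
}

#' @export
print.chi_matrix <- function(x, ...) {
  cat("<chi_matrix> ", nrow(x), " modes", sep = "")
  rm_ <- attr(x, "removed")
  if (!is.null(rm_) && NROW(rm_) > 0) cat(" (", NROW(rm_), " Fermi fraction(s) removed)", sep = "")
  cat("\n")
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x))], ...)
  invisible(x)
}
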