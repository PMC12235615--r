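# VPT2 transition moments by explicit Rayleigh-Schrodinger perturbation
# theory in the harmonic-oscillator product basis.
#
# With the usual perturbative ordering (cubic potential ~ lambda, quartic ~
# lambda^2, dipole derivatives d1/d2/d3 of orders 0/1/2) the ground-to-state
# moment <psi_0|mu|psi_f> is assembled term by term:
#   fundamentals   : all terms through second order, including the mixed
#                    electrical-mechanical d2 x psi^(1) contributions;
#   2-quanta states: all terms through first order (d2 with harmonic wave
#                    functions + d1 with first-order wave functions), so the
#                    full moment splits exactly into mechanical + electrical.
# Every energy denominator E_n - E_v is a known signed combination of
# harmonic wavenumbers; a flagged resonance (Fermi or Darling-Dennison)
# removes precisely the terms carrying that combination, which reproduces
# the deperturbed (IDVPT2) moments.

canonical_delta_key <- function(delta) {
  nz <- which(delta != 0)
  if (length(nz) && delta[nz[1]] < 0) delta <- -delta
  paste(delta, collapse = ",")
}

# first-order wavefunction of |n>: components v with coefficient
# <v|V3|n>/(E_n - E_v), flagged combinations skipped
rspt_psi1 <- function(nq, V3, omega, removed_keys = character(0)) {
  out <- op_apply(V3, sparse_state(nq))
  if (!length(out$coef)) return(out)
  keep <- logical(length(out$coef))
  dens <- numeric(length(out$coef))
  for (r in seq_along(out$coef)) {
    delta <- as.integer(nq) - out$quanta[r, ]
    den <- sum(delta * omega)
    if (all(delta == 0L)) next
    if (canonical_delta_key(delta) %in% removed_keys) next
    if (den == 0)
      stop("exact degeneracy in an unflagged first-order denominator; flag the resonance")
    keep[r] <- TRUE; dens[r] <- den
  }
  list(quanta = out$quanta[keep, , drop = FALSE],
       coef = out$coef[keep] / dens[keep])
}

# second-order wavefunction of |n> (V4 first order + V3 twice); returns the
# component list plus the normalization coefficient -1/2 sum c1^2 that
# multiplies |n> itself
rspt_psi2 <- function(nq, V3, V4, omega, removed_keys = character(0),
                      psi1 = NULL) {
  nq <- as.integer(nq)
  if (is.null(psi1)) psi1 <- rspt_psi1(nq, V3, omega, removed_keys)
  pieces_q <- list(); pieces_c <- list()
  add_filtered <- function(out) {
    if (!length(out$coef)) return()
    keep <- logical(length(out$coef)); dens <- numeric(length(out$coef))
    for (r in seq_along(out$coef)) {
      delta <- nq - out$quanta[r, ]
      if (all(delta == 0L)) next
      if (canonical_delta_key(delta) %in% removed_keys) next
      den <- sum(delta * omega)
      if (den == 0)
        stop("exact degeneracy in an unflagged second-order denominator; flag the resonance")
      keep[r] <- TRUE; dens[r] <- den
    }
    pieces_q[[length(pieces_q) + 1]] <<- out$quanta[keep, , drop = FALSE]
    pieces_c[[length(pieces_c) + 1]] <<- out$coef[keep] / dens[keep]
  }
  add_filtered(op_apply(V4, sparse_state(nq)))
  if (length(psi1$coef)) {
    for (r in seq_along(psi1$coef)) {
      add_filtered(op_apply(V3, sparse_state(psi1$quanta[r, , drop = FALSE],
                                             psi1$coef[r])))
    }
  }
  comps <- if (length(pieces_q)) {
    sparse_collect(list(quanta = do.call(rbind, pieces_q), coef = unlist(pieces_c)))
  } else sparse_state(matrix(integer(0), 0, length(nq)), numeric(0))
  list(components = comps, norm_coef = -sum(psi1$coef^2) / 2, psi1 = psi1)
}

#' VPT2 transition moments from the ground state, all flavors
#'
#' Computes \eqn{\langle\psi_0|\mu|\psi_f\rangle} (debye, 3 components) for a
#' 1- or 2-quanta state in four flavors: \code{harm} (double-harmonic),
#' \code{mech} (wave-function/cubic-force-constant anharmonicity only, dipole
#' truncated at first derivatives), \code{elec} (dipole-expansion
#' anharmonicity only, harmonic wave functions) and \code{full} (all terms,
#' including the mixed electrical-mechanical contributions for fundamentals).
#' Flagged resonant denominators are removed (IDVPT2 moments).
#'
#' @param state quanta vector, total quanta 1 or 2.
#' @param ff an \code{\link{anharmonic_ff}}.
#' @param dip a \code{\link{dipole_surface}}.
#' @param removed_keys canonical resonance-combination keys to remove, as
#'   produced by \code{\link{registry_keys}}; empty for plain VPT2.
#' @param ops precomputed \code{ff_operators(ff)} (optional).
#' @return list with one 3-vector per flavor (\code{full}, \code{mech},
#'   \code{elec}, \code{harm}).
#' @export
vpt2_moments <- function(state, ff, dip, removed_keys = character(0), ops = NULL) {
  nq <- as.integer(state)
  ntot <- sum(nq)
  if (!ntot %in% 1:2)
    stop("direct VPT2 transition moments are implemented for 1- and 2-quanta states")
  omega <- ff$omega
  M <- length(omega)
  if (is.null(ops)) ops <- ff_operators(ff)
  V3 <- ops$V3; V4 <- ops$V4
  s0 <- sparse_state(rep(0L, M))
  sf <- sparse_state(nq)
  p0_1 <- rspt_psi1(rep(0L, M), V3, omega, removed_keys)
  pf_1 <- rspt_psi1(nq, V3, omega, removed_keys)
  if (ntot == 1) {
    p0_2 <- rspt_psi2(rep(0L, M), V3, V4, omega, removed_keys, psi1 = p0_1)
    pf_2 <- rspt_psi2(nq, V3, V4, omega, removed_keys, psi1 = pf_1)
    norm_corr <- p0_2$norm_coef + pf_2$norm_coef
  }
  res <- list(full = numeric(3), mech = numeric(3), elec = numeric(3),
              harm = numeric(3))
  for (comp in 1:3) {
    mu1 <- dipole_operator(dip, comp, "mu1")
    mu2 <- dipole_operator(dip, comp, "mu2")
    mu3 <- dipole_operator(dip, comp, "mu3")
    bk <- function(bra, op, ket) {
      if (!length(op$coef) || !length(bra$coef) || !length(ket$coef)) return(0)
      sparse_dot(bra, op_apply(op, ket))
    }
    m_harm <- bk(s0, mu1, sf)
    m_mech1 <- bk(p0_1, mu1, sf) + bk(s0, mu1, pf_1)
    m_elec <- bk(s0, mu2, sf) + if (ntot == 1) bk(s0, mu3, sf) else 0
    if (ntot == 1) {
      m_mech2 <- bk(p0_2$components, mu1, sf) + bk(s0, mu1, pf_2$components) +
        bk(p0_1, mu1, pf_1) + norm_corr * m_harm
      m_mixed <- bk(p0_1, mu2, sf) + bk(s0, mu2, pf_1)
      res$harm[comp] <- m_harm
      res$mech[comp] <- m_harm + m_mech1 + m_mech2
      res$elec[comp] <- m_harm + m_elec
      res$full[comp] <- m_harm + m_mech1 + m_mech2 + m_elec + m_mixed
    } else {
      res$harm[comp] <- m_harm            # zero by parity
      res$mech[comp] <- m_harm + m_mech1
      res$elec[comp] <- m_elec
      res$full[comp] <- m_harm + m_mech1 + m_elec
    }
  }
  res
}

#' Single-flavor VPT2 transition moment
#'
#' Convenience wrapper around \code{\link{vpt2_moments}}.
#'
#' @inheritParams vpt2_moments
#' @param flavor one of \code{"full"}, \code{"mech"}, \code{"elec"},
#'   \code{"harm"}.
#' @return 3-vector, debye.
#' @export
vpt2_transition_moment <- function(state, ff, dip, flavor = c("full", "mech", "elec", "harm"),
                                   removed_keys = character(0)) {
  flavor <- match.arg(flavor)
  vpt2_moments(state, ff, dip, removed_keys)[[flavor]]
}
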