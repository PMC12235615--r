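test_that("one-mode chi reduces to f4/16 without cubic forces", {
  ff <- anharmonic_ff(1500, array(0, c(1, 1, 1)), array(8, c(1, 1, 1)))
  expect_equal(vpt2_chi(ff)[1, 1], 0.5)
})

test_that("VPT2 on the Morse quartic truncation reproduces the exact Morse ladder", {
  omega <- 1600; D <- 64000
  toy <- morse_ff(omega, D)
  chi <- vpt2_chi(toy$ff)
  expect_equal(chi[1, 1], -omega^2 / (4 * D), tolerance = 1e-12)
  fund <- vpt2_transition_energy(1, omega, chi)
  over <- vpt2_transition_energy(2, omega, chi)
  expect_rel_equal(fund, morse_levels(1, omega, D), 1e-10)
  expect_rel_equal(over, morse_levels(2, omega, D), 1e-10)
})

test_that("transition energies recover the harmonic limit and the chi additivity identity", {
  omega <- c(1700, 1100, 500)
  chi0 <- matrix(0, 3, 3)
  expect_equal(vpt2_transition_energy(c(1, 0, 2), omega, chi0),
               1700 + 2 * 500)
  toy <- random_ff(3, seed = 21)
  chi <- vpt2_chi(toy$ff)
  om <- toy$ff$omega
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    comb <- vpt2_transition_energy(qv(3, c(i, 1), c(j, 1)), om, chi)
    vi <- vpt2_transition_energy(qv(3, c(i, 1)), om, chi)
    vj <- vpt2_transition_energy(qv(3, c(j, 1)), om, chi)
    expect_equal(comb - vi - vj, chi[i, j], tolerance = 1e-10)
  }
})

test_that("an exactly resonant unflagged denominator is an error instructing to flag", {
  toy <- coupled_fermi_ff(delta = 0, f122 = 40)
  expect_error(vpt2_chi(toy$ff), "flag the Fermi triple")
  # flagged: finite and deperturbed
  chi <- vpt2_chi(toy$ff, removed = cbind(1, 2, 2))
  expect_true(all(is.finite(chi)))
})

test_that("removed fraction equals the singular part extracted by a detuning limit study", {
  # chi_12 with the (1,(2,2)) fraction removed must equal the eps -> 0 limit
  # of the unflagged chi_12 after subtracting the analytic singular fraction
  f122 <- 40
  chi_d <- vpt2_chi(coupled_fermi_ff(delta = 0, f122 = f122)$ff,
                    removed = cbind(1, 2, 2))[1, 2]
  resid <- function(eps) {
    toy <- coupled_fermi_ff(delta = eps, f122 = f122)
    om <- toy$ff$omega
    sing <- -f122^2 / 8 / (2 * om[2] - om[1])   # the removable fraction of chi_12
    vpt2_chi(toy$ff)[1, 2] - sing
  }
  expect_equal(resid(1e-3), chi_d, tolerance = 1e-4)
  expect_equal(resid(1e-5), chi_d, tolerance = 1e-6)
})

test_that("deperturbed chi with an empty registry equals plain VPT2", {
  toy <- random_ff(3, seed = 31)
  expect_equal(unclass(vpt2_chi(toy$ff, removed = NULL)),
               unclass(vpt2_chi(toy$ff, removed = matrix(integer(0), 0, 3))),
               ignore_attr = TRUE)
})

test_that("VPT2 energies agree with the VCI oracle on weakly anharmonic fields", {
  for (seed in c(3, 14, 27)) {
    toy <- random_ff(3, seed = seed)
    chi <- vpt2_chi(toy$ff)
    v <- vci_solve(toy$ff, toy$dip, basis_max_quanta = 12,
                   check_convergence = FALSE)
    st <- enumerate_states(toy$ff$omega, 2)
    for (r in seq_len(nrow(st))) {
      e_pt <- vpt2_transition_energy(st[r, ], toy$ff$omega, chi)
      expect_lt(abs(e_pt - vci_state_of(v, st[r, ])$energy), 1)
    }
  }
})

test_that("harmonic-limit moments and pure-electrical overtones match closed forms", {
  # fundamental with zero anharmonicity: mu = d1/sqrt(2) in every flavor
  omega <- c(1600, 900)
  ff <- anharmonic_ff(omega, array(0, c(2, 2, 2)), array(0, c(2, 2, 2)))
  d1 <- rbind(c(0.4, 0.1, 0), c(0, 0.2, 0.1))
  d2 <- array(0, c(2, 2, 3)); d2[1, 1, 1] <- 0.06; d2[1, 2, 2] <- d2[2, 1, 2] <- 0.04
  dip <- dipole_surface(d1 = d1, d2 = d2)
  m <- vpt2_moments(c(1, 0), ff, dip)
  for (fl in c("full", "mech", "elec", "harm"))
    expect_equal(m[[fl]], d1[1, ] / sqrt(2), tolerance = 1e-12)
  # overtone with all cubic constants zero: electrical only, d2_ii/(2 sqrt 2)
  m2 <- vpt2_moments(c(2, 0), ff, dip)
  expect_equal(m2$elec[1], d2[1, 1, 1] / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(m2$full, m2$elec, tolerance = 1e-12)
  expect_equal(m2$mech, rep(0, 3))
  # combination: d2_ij/2
  mc <- vpt2_moments(c(1, 1), ff, dip)
  expect_equal(mc$full[2], d2[1, 2, 2] / 2, tolerance = 1e-12)
})

test_that("flavor algebra holds: 2-quanta full = mech + elec; mixed term vanishes as required", {
  toy <- random_ff(3, seed = 8)
  st2 <- list(c(2, 0, 0), c(1, 1, 0), c(0, 1, 1))
  for (s in st2) {
    m <- vpt2_moments(s, toy$ff, toy$dip)
    expect_equal(m$full, m$mech + m$elec, tolerance = 1e-12)
  }
  # fundamentals: mixed term = full - harm - (mech-harm) - (elec-harm)
  mixed_of <- function(toy) {
    m <- vpt2_moments(c(1, 0, 0), toy$ff, toy$dip)
    m$full - m$harm - (m$mech - m$harm) - (m$elec - m$harm)
  }
  expect_gt(max(abs(mixed_of(toy))), 0)       # generically nonzero
  # vanishes when the dipole expansion is linear
  toy_lin <- toy
  toy_lin$dip <- dipole_surface(d1 = toy$dip$d1)
  expect_equal(mixed_of(toy_lin), rep(0, 3))
  # vanishes when cubic constants vanish
  toy_nc <- toy
  toy_nc$ff$cubic[] <- 0
  expect_equal(mixed_of(toy_nc), rep(0, 3))
})

test_that("full VPT2 moments track the VCI oracle", {
  # weakly anharmonic 3-mode toys: fundamentals tight, 2-quanta within 5%
  for (seed in c(3, 14)) {
    toy <- random_ff(3, seed = seed)
    v <- vci_solve(toy$ff, toy$dip, basis_max_quanta = 12,
                   check_convergence = FALSE)
    st <- enumerate_states(toy$ff$omega, 2)
    for (r in seq_len(nrow(st))) {
      m <- sqrt(sum(vpt2_moments(st[r, ], toy$ff, toy$dip)$full^2))
      vm <- sqrt(sum(vci_state_of(v, st[r, ])$moment^2))
      tol <- if (sum(st[r, ]) == 1) 0.001 else 0.05
      expect_lt(abs(m - vm) / vm, tol)
    }
  }
})

test_that("Morse-like overtone intensity is entirely mechanical and matches VCI", {
  # linear dipole only: the overtone moment exists solely through the cubic
  # wave-function correction
  omega <- 1600; D <- omega^2 / (4 * 10)   # omega*x_e = 10, D/omega = 40
  toy <- morse_ff(omega, D, dipole_linear = 0.3, dipole_quadratic = 0)
  m <- vpt2_moments(c(2), toy$ff, toy$dip)
  expect_equal(m$elec, rep(0, 3))
  expect_equal(m$full, m$mech, tolerance = 1e-14)
  v <- vci_solve(toy$ff, toy$dip, basis_max_quanta = 40,
                 check_convergence = FALSE)
  I_pt <- ir_intensity(vpt2_transition_energy(2, omega, vpt2_chi(toy$ff)),
                       m$full)
  vs <- vci_state_of(v, 2)
  I_vci <- ir_intensity(vs$energy, vs$moment)
  expect_lt(abs(I_pt - I_vci) / I_vci, 0.02)
})

test_that("direct moments are restricted to at most two quanta", {
  toy <- random_ff(2, seed = 5)
  expect_error(vpt2_moments(c(2, 1), toy$ff, toy$dip), "1- and 2-quanta")
})
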