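test_that("AFF files round-trip bit-identically", {
  toy <- random_ff(3, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".aff")
  f2 <- withr::local_tempfile(fileext = ".aff")
  write_aff(toy$basis, toy$ff, toy$dip, f1)
  rt <- read_aff(f1)
  expect_identical(rt$basis$omega, toy$basis$omega)
  expect_identical(rt$ff$cubic[seq_along(rt$ff$cubic)],
                   toy$ff$cubic[seq_along(toy$ff$cubic)])
  expect_identical(rt$dip$d2[seq_along(rt$dip$d2)],
                   toy$dip$d2[seq_along(toy$dip$d2)])
  write_aff(rt$basis, rt$ff, rt$dip, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("conflicting permuted cubic records are a validation error naming the indices", {
  toy <- morse_ff(1600, 64000)
  f <- withr::local_tempfile(fileext = ".aff")
  write_aff(toy$basis, toy$ff, toy$dip, f)
  # forge a 2-mode file with inconsistent f_121 vs f_112
  lines <- readLines(f)
  lines <- sub("^modes 1$", "modes 2", lines)
  txt <- c("[meta]", "version 1", "modes 2", "atoms 3", "level_tag forged",
           "[atoms]", rep("1.0 0 0 0", 3),
           "[modes]", apply(diag(9)[, 1:2], 1, paste, collapse = " "),
           "[omega]", "1600.0", "800.0",
           "[cubic]", "1 1 2 5.0", "1 2 1 5.01",
           "[quartic]",
           "[dipole1]", "1 0.1 0 0", "2 0.05 0 0")
  writeLines(txt, f)
  expect_error(read_aff(f), "\\(1,1,2\\)")
})

test_that("missing sections are parse errors naming the section", {
  f <- withr::local_tempfile(fileext = ".aff")
  writeLines(c("[meta]", "version 1", "modes 1", "atoms 3"), f)
  expect_error(read_aff(f), "\\[atoms\\]")
  expect_error(read_aff("no/such/file.aff"), "not found")
})

test_that("Morse fixture survives serialization with analytic constants intact", {
  omega <- 1600; D <- 64000
  toy <- morse_ff(omega, D)
  f <- withr::local_tempfile(fileext = ".aff")
  write_aff(toy$basis, toy$ff, toy$dip, f)
  rt <- read_aff(f)
  alpha <- sqrt(omega / (2 * D))
  expect_equal(rt$ff$cubic[1, 1, 1], -6 * D * alpha^3, tolerance = 1e-13)
  expect_equal(rt$ff$quartic[1, 1, 1], 14 * D * alpha^4, tolerance = 1e-13)
  expect_equal(rt$basis$omega, omega)
})

test_that("central differences are exact on exactly quartic potentials", {
  toy <- random_ff(3, seed = 4)
  ffq <- toy$ff
  M <- 3
  q4 <- function(a, b, c_, d_) {
    ix <- sort(c(a, b, c_, d_))
    if (max(table(ix)) < 2) return(0)
    gvpt2:::quartic_entry(ffq$quartic, ix)
  }
  hess_at <- function(q) {
    H <- diag(ffq$omega)
    for (a in 1:M) for (b in 1:M) {
      v <- sum(vapply(1:M, function(c_) ffq$cubic[a, b, c_] * q[c_], 0))
      for (c_ in 1:M) for (d_ in 1:M) v <- v + 0.5 * q4(a, b, c_, d_) * q[c_] * q[d_]
      H[a, b] <- H[a, b] + v
    }
    H
  }
  for (del in c(0.01, 0.3)) {   # any step works on a quartic potential
    out <- aff_from_displacements(list(
      step = del, hess0 = hess_at(rep(0, M)),
      hess_plus = lapply(1:M, function(i) hess_at(replace(rep(0, M), i, del))),
      hess_minus = lapply(1:M, function(i) hess_at(replace(rep(0, M), i, -del))),
      omega = ffq$omega))
    expect_lt(max(abs(out$ff$cubic - ffq$cubic)), 1e-9)
    expect_lt(max(abs(out$ff$quartic - ffq$quartic)), 1e-7)
  }
})

test_that("finite differences on a Morse curve converge at second order", {
  omega <- 1600; D <- 64000
  alpha <- sqrt(omega / (2 * D))
  vpp <- function(q) D * (-2 * alpha^2 * exp(-alpha * q) + 4 * alpha^2 * exp(-2 * alpha * q))
  err_at <- function(del) {
    out <- aff_from_displacements(list(
      step = del, hess0 = matrix(vpp(0), 1, 1),
      hess_plus = list(matrix(vpp(del), 1, 1)),
      hess_minus = list(matrix(vpp(-del), 1, 1)),
      omega = omega))
    c(f3 = abs(out$ff$cubic[1, 1, 1] - (-6 * D * alpha^3)),
      f4 = abs(out$ff$quartic[1, 1, 1] - 14 * D * alpha^4))
  }
  e1 <- err_at(0.02); e2 <- err_at(0.01)
  expect_lt(e2["f3"], 1e-3)                 # O(delta^2) error, small at 0.01
  expect_equal(unname(e1["f3"] / e2["f3"]), 4, tolerance = 0.05)
  expect_equal(unname(e1["f4"] / e2["f4"]), 4, tolerance = 0.05)
})

test_that("harmonic input yields exactly zero anharmonic constants", {
  H0 <- diag(c(1500, 900))
  out <- aff_from_displacements(list(
    step = 0.05, hess0 = H0,
    hess_plus = list(H0, H0), hess_minus = list(H0, H0),
    omega = diag(H0)))
  expect_true(all(out$ff$cubic == 0))
  expect_true(all(out$ff$quartic == 0))
})

test_that("missing displacements are reported with mode and sign", {
  H0 <- diag(c(1500, 900))
  expect_error(aff_from_displacements(list(
    step = 0.05, hess0 = H0,
    hess_plus = list(H0, NULL), hess_minus = list(H0, H0))),
    "mode 2, sign \\+")
})

test_that("reduced-unit conversion maps harmonic force constants onto wavenumbers", {
  # identity when already reduced
  basis <- gvpt2:::toy_basis(c(1600))
  x <- array(runif(1), dim = c(1, 1))
  expect_identical(to_reduced_units(x, basis, "reduced"), x)
  expect_error(to_reduced_units(x, basis, "bohr"), "unknown unit tag")

  # 1D harmonic Hessian in mass-weighted units: k = omega * q_scale(omega)^2
  # (cm^-1 per u Angstrom^2); reduced second derivative must be omega itself
  omega <- 1600
  k_mw <- omega * q_scale(omega)^2
  red <- to_reduced_units(matrix(k_mw, 1, 1), basis)
  expect_equal(red[1, 1], omega, tolerance = 1e-12)
})

test_that("mass scaling propagates consistently through the q definition", {
  # doubling all masses at fixed Cartesian force constants: omega -> omega/sqrt(2),
  # mass-weighted cubic -> cubic/2^(3/2); reduced cubic must then rescale as
  # phi / (s(omega')^3) with the new scale factors
  omega <- 1200; phi_mw <- 7.5            # some mass-weighted cubic, cm^-1/(sqrt(u) A)^3
  b1 <- gvpt2:::toy_basis(omega)
  f1 <- to_reduced_units(array(phi_mw, c(1, 1, 1)), b1)[1, 1, 1]
  omega2 <- omega / sqrt(2)
  b2 <- gvpt2:::toy_basis(omega2)
  f2 <- to_reduced_units(array(phi_mw / 2^(3 / 2), c(1, 1, 1)), b2)[1, 1, 1]
  # symbolic law: f_red scales as phi_mw / s^3 with s ~ sqrt(omega)
  expect_equal(f2, f1 / 2^(3 / 2) * (q_scale(omega) / q_scale(omega2))^3,
               tolerance = 1e-12)
})

test_that("mass-weighted steps convert per mode", {
  expect_equal(reduced_step(0.01, 1000), 0.01 * q_scale(1000))
  expect_gt(reduced_step(0.01, 1600), reduced_step(0.01, 400))
})
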