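worked_example_ff <- function(f123 = 30, omega = c(1400, 700, 710)) {
  cubic <- array(0, c(3, 3, 3))
  for (p in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)))
    cubic[p[1], p[2], p[3]] <- f123
  anharmonic_ff(omega, cubic, array(0, c(3, 3, 3)))
}

test_that("Fermi detection reproduces the hand-computed diagnostics of the worked example", {
  ff <- worked_example_ff()
  edges <- detect_fermi(ff$omega, ff$cubic)
  e <- edges[edges$i == 1 & edges$j == 2 & edges$k == 3, ]
  expect_equal(nrow(e), 1)
  expect_equal(e$delta, -10)
  expect_equal(e$depth, 30^4 / (64 * 1 * 10^3))   # 12.656...
  expect_equal(e$ratio, 30 / 80)                  # 0.375
  expect_true(e$accepted)
  expect_equal(e$W, 30 / (2 * sqrt(2)))
})

test_that("the detuning window rejects far-off candidates regardless of the coupling", {
  ff <- worked_example_ff(f123 = 500, omega = c(1000, 700, 710))   # delta = -410
  edges <- detect_fermi(ff$omega, ff$cubic)
  e <- edges[edges$i == 1 & edges$j == 2 & edges$k == 3, ]
  expect_false(e$accepted)
  # diagnostics still reported for the rejected candidate
  expect_true(is.finite(e$depth) && is.finite(e$ratio))
})

test_that("exact degeneracy auto-accepts with infinite diagnostics", {
  omega <- c(1400, 700, 700)
  cubic <- array(0, c(3, 3, 3))
  cubic[1, 2, 2] <- cubic[2, 1, 2] <- cubic[2, 2, 1] <- 30
  ff <- anharmonic_ff(omega, cubic, array(0, c(3, 3, 3)))
  edges <- detect_fermi(ff$omega, ff$cubic)
  e <- edges[edges$i == 1 & edges$j == 2 & edges$k == 2, ]
  expect_true(e$accepted)
  expect_equal(e$delta, 0)
  expect_true(is.infinite(e$depth) && is.infinite(e$ratio))
  expect_equal(e$W, 30 / 4)
})

test_that("Fermi couplings follow the closed forms and vanish without constants", {
  # i vs j^1 k^1: W = f/(2 sqrt 2)
  ff <- worked_example_ff(f123 = 28.28)
  W <- resonance_coupling(c(1, 0, 0), c(0, 1, 1), ff)
  expect_equal(W, 28.28 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(W, 10, tolerance = 1e-2)
  # symmetric in bra and ket
  expect_equal(resonance_coupling(c(0, 1, 1), c(1, 0, 0), ff), W)
  # i vs j^2: W = f_ijj/4
  omega <- c(1400, 700)
  cubic <- array(0, c(2, 2, 2))
  cubic[1, 2, 2] <- cubic[2, 1, 2] <- cubic[2, 2, 1] <- 40
  ff2 <- anharmonic_ff(omega, cubic, array(0, c(2, 2, 2)))
  expect_equal(resonance_coupling(c(1, 0), c(0, 2), ff2), 10)
  # all constants zero
  ff0 <- anharmonic_ff(omega, array(0, c(2, 2, 2)), array(0, c(2, 2, 2)))
  expect_equal(resonance_coupling(c(1, 0), c(0, 2), ff0), 0)
  edges <- detect_resonances(ff0)
  expect_equal(sum(edges$accepted), 0)
})

test_that("a constructed 1-1 Darling-Dennison pair is detected and its mixing confirmed variationally", {
  # two fundamentals 5 cm^-1 apart, coupled through the direct quartic
  # f_1112 (first-order in V4, part of the contact-transformed coupling)
  omega <- c(1502.5, 1497.5, 700)
  quartic <- array(0, c(3, 3, 3))
  quartic[1, 1, 2] <- quartic[1, 2, 1] <- 100   # f_1112
  ff <- anharmonic_ff(omega, array(0, c(3, 3, 3)), quartic)
  W <- resonance_coupling(c(1, 0, 0), c(0, 1, 0), ff)
  # <1_1|(f/6) q1^3 q2|1_2> = (f/6)(3/(2 sqrt 2))(1/sqrt 2) = f/8
  expect_equal(W, 100 / 8, tolerance = 1e-10)
  edges <- detect_dd(ff, "dd11")
  e <- edges[edges$i == 1 & edges$j == 2, ]
  expect_true(e$accepted)
  expect_equal(e$W, W)
  # two-state mixing against VCI: strong 50/50-like doublet
  dip <- dipole_surface(d1 = rbind(c(0.3, 0, 0), c(0, 0, 0), c(0, 0.1, 0)))
  v <- vci_solve(ff, dip, basis_max_quanta = 10, check_convergence = FALSE)
  s1 <- vci_state_of(v, c(1, 0, 0))
  expect_lt(s1$weight, 0.75)                   # heavily mixed
  # 2x2 model: splitting ~ sqrt(delta^2 + 4 W^2)
  s2 <- vci_state_of(v, c(0, 1, 0))
  expect_equal(abs(s1$energy - s2$energy), sqrt(5^2 + 4 * W^2), tolerance = 0.02)
})

test_that("2-2 candidates outside the window are rejected whatever the coupling", {
  omega <- c(1500, 1425, 700)   # |2w1 - 2w2| = 150 > 100
  quartic <- array(0, c(3, 3, 3))
  quartic[1, 2, 2] <- quartic[2, 1, 1] <- 400
  ff <- anharmonic_ff(omega, array(0, c(3, 3, 3)), quartic)
  edges <- detect_dd(ff, "dd22")
  e <- edges[edges$bra == "1^2" & edges$ket == "2^2", ]
  expect_false(e$accepted)
})

test_that("polyads are the connected components of the accepted-edge graph", {
  omega <- c(2110, 1060, 1050, 530)
  st <- enumerate_states(omega, 2)
  # edges 1^1 ~ 2^1 3^1 (fermi) and 2^1 3^1 ~ 4^2 wired via a crafted frame
  edges <- rbind(
    data.frame(kind = "fermi", i = 1, j = 2, k = 3, l = NA, bra = "1^1",
               ket = "2^1 3^1", delta = 0, W = 10, depth = Inf, ratio = Inf,
               cmix = NA, accepted = TRUE),
    data.frame(kind = "dd22", i = 2, j = 3, k = 4, l = 4, bra = "2^1 3^1",
               ket = "4^2", delta = 50, W = 12, depth = NA, ratio = NA,
               cmix = NA, accepted = TRUE),
    data.frame(kind = "dd11", i = 2, j = 3, k = NA, l = NA, bra = "2^1",
               ket = "3^1", delta = 10, W = 1, depth = NA, ratio = NA,
               cmix = 0.1, accepted = FALSE))
  polyads <- build_polyads(st, edges)
  expect_equal(length(polyads), 1)
  labs <- rownames(st)[polyads[[1]]]
  expect_setequal(labs, c("1^1", "2^1 3^1", "4^2"))   # transitive closure
  expect_equal(nrow(attr(polyads[[1]], "edges")), 2)
  # no accepted edges -> no polyads
  expect_equal(length(build_polyads(st, edges[edges$kind == "dd11", ])), 0)
})

test_that("a pairwise-linked chain forms a single polyad", {
  omega <- rep(1000, 12) + seq(0, 22, by = 2)
  st <- enumerate_states(omega, 1)
  edges <- do.call(rbind, lapply(1:11, function(i)
    data.frame(kind = "dd11", i = i, j = i + 1, k = NA, l = NA,
               bra = sprintf("%d^1", i), ket = sprintf("%d^1", i + 1),
               delta = 2, W = 15, depth = NA, ratio = NA, cmix = 7.5,
               accepted = TRUE)))
  polyads <- build_polyads(st, edges)
  expect_equal(length(polyads), 1)
  expect_equal(length(polyads[[1]]), 12)
})

test_that("variational correction: degenerate doublet, trace conservation, dark-state borrowing", {
  st <- enumerate_states(c(1600, 800), 2)
  E <- 1590
  edges <- data.frame(kind = "fermi", i = 1, j = 2, k = 2, l = NA, bra = "1^1",
                      ket = "2^2", delta = 0, W = 10, depth = Inf, ratio = Inf,
                      cmix = NA, accepted = TRUE)
  members <- match(c("2^2", "1^1"), rownames(st))
  energies <- stats::setNames(rep(0, nrow(st)), rownames(st))
  energies[members] <- c(E, E)
  mu <- matrix(0, nrow(st), 3); mu[match("1^1", rownames(st)), 1] <- 0.5
  vc <- variational_correct(members, st, edges, energies, list(full = mu))
  expect_equal(vc$energies, c(E - 10, E + 10))
  expect_equal(abs(vc$vectors), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12)
  # trace conservation
  expect_rel_equal(sum(vc$energies), sum(diag(vc$matrix)), 1e-12)
  # dark state borrows intensity; squared-moment norm conserved exactly
  m2 <- rowSums(vc$moments$full^2)
  expect_true(all(m2 > 0))
  expect_rel_equal(sum(m2), 0.5^2, 1e-12)
})

test_that("composition strings follow the ket convention with the 0.2 print threshold", {
  expect_equal(describe_polyad(c(0.953), "7^1"), "0.953 |7^1>")
  expect_equal(describe_polyad(c(-0.953), "7^1"), "0.953 |7^1>")  # leading sign normalized
  s <- describe_polyad(c(1, 1) / sqrt(2), c("A", "B"))
  expect_equal(s, "0.707 |A> + 0.707 |B>")
  # coefficient below threshold omitted from the string
  c_ <- c(sqrt(1 - 0.19^2), 0.19)
  expect_false(grepl("0.190", describe_polyad(c_, c("A", "B"))))
  expect_true(grepl("0.190", describe_polyad(c_, c("A", "B"), c_min = 0.1)))
})

test_that("loosening thresholds never removes accepted edges; zero windows give plain VPT2", {
  toy <- random_ff(3, seed = 42, resonant = TRUE)
  th_tight <- resonance_thresholds()
  th_loose <- resonance_thresholds(fermi_window = 400, fermi_depth = 0.5,
                                   fermi_ratio = 0.05, dd_window = 200,
                                   dd_coupling = 5, dd11_cmix = 0.5,
                                   dd13_cmix = 0.15)
  e_t <- detect_resonances(toy$ff, th_tight)
  e_l <- detect_resonances(toy$ff, th_loose)
  key <- function(e) paste(e$kind, e$bra, e$ket)
  expect_true(all(key(e_t)[e_t$accepted] %in% key(e_l)[e_l$accepted]))

  th_zero <- resonance_thresholds(fermi_window = 0, dd_window = 0)
  toy2 <- random_ff(3, seed = 9)
  fit_z <- gvpt2(toy2$ff, toy2$dip, thresholds = th_zero)
  fit_v <- gvpt2(toy2$ff, toy2$dip, method = "vpt2")
  expect_equal(fit_z$states$energy, fit_v$states$energy, tolerance = 1e-14)
  expect_equal(fit_z$intensity$full, fit_v$intensity$full, tolerance = 1e-14)
})

test_that("GVPT2 indices follow corrected energies when a polyad reorders states", {
  # strong coupling pushes the lower doublet member below a bystander state
  omega <- c(1600, 805, 795)
  cubic <- array(0, c(3, 3, 3))
  cubic[1, 2, 3] <- cubic[1, 3, 2] <- cubic[2, 1, 3] <- cubic[2, 3, 1] <-
    cubic[3, 1, 2] <- cubic[3, 2, 1] <- 80
  ff <- anharmonic_ff(omega, cubic, array(0, c(3, 3, 3)))
  dip <- dipole_surface(d1 = rbind(c(0.3, 0, 0), c(0.1, 0, 0), c(0.05, 0, 0)))
  fit <- gvpt2(ff, dip)
  expect_false(is.unsorted(fit$states$energy))
  expect_equal(fit$states$index, seq_len(nrow(fit$states)))
})
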