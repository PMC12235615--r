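# shared helpers for oracle comparisons

# transition energy / moment of the VCI eigenstate dominated by the given
# harmonic basis state
vci_state_of <- function(v, quanta) {
  keys <- apply(v$basis, 1, paste, collapse = ",")
  i <- match(paste(as.integer(quanta), collapse = ","), keys)
  k <- which.max(abs(v$vectors[i, ]))
  list(energy = v$transition_energy[k],
       moment = v$moments[k, ],
       weight = v$vectors[i, k]^2,
       index = k)
}

# quanta vector with single excitations
qv <- function(M, ...) {
  q <- integer(M)
  ex <- list(...)
  for (e in ex) q[e[1]] <- q[e[1]] + as.integer(e[2])
  q
}

with_seed_local <- function(seed, code) gvpt2:::with_seed(seed, code)

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.eps)), tol)
}
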