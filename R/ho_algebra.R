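# Sparse ladder-operator algebra in the harmonic-oscillator product basis.
#
# A sparse wavefunction is a list(quanta = integer matrix [ncomp x M],
# coef = numeric).  Operators are lists of monomials c_t * prod_i q_i^{p_ti},
# represented as list(coef = numeric, powers = integer matrix [nterm x M]).
# Matrix elements of q are exact: <n+1|q|n> = sqrt((n+1)/2),
# <n-1|q|n> = sqrt(n/2).

sparse_state <- function(quanta, coef = 1) {
  if (is.null(dim(quanta))) quanta <- matrix(as.integer(quanta), nrow = 1)
  list(quanta = quanta, coef = as.numeric(coef))
}

# merge duplicate components
sparse_collect <- function(st, drop_tol = 0) {
  if (nrow(st$quanta) == 0) return(st)
  keys <- apply(st$quanta, 1, paste, collapse = ",")
  agg <- rowsum(st$coef, keys)
  keep <- which(abs(agg[, 1]) > drop_tol)
  kq <- rownames(agg)[keep]
  first <- match(kq, keys)
  list(quanta = st$quanta[first, , drop = FALSE], coef = as.numeric(agg[keep, 1]))
}

# apply q_mode once to every component
apply_q_once <- function(st, mode) {
  n <- st$quanta[, mode]
  up <- st$quanta; up[, mode] <- n + 1L
  cu <- st$coef * sqrt((n + 1) / 2)
  has_dn <- n > 0L
  dn <- st$quanta[has_dn, , drop = FALSE]
  dn[, mode] <- n[has_dn] - 1L
  cd <- st$coef[has_dn] * sqrt(n[has_dn] / 2)
  list(quanta = rbind(up, dn), coef = c(cu, cd))
}

# apply a monomial prod q_i^{p_i}
apply_monomial <- function(st, powers) {
  for (m in which(powers > 0)) {
    for (r in seq_len(powers[m])) st <- apply_q_once(st, m)
  }
  sparse_collect(st)
}

# apply a full operator (sum of monomials) to a sparse state
op_apply <- function(op, st) {
  if (length(op$coef) == 0) return(sparse_state(st$quanta[0, , drop = FALSE], numeric(0)))
  qs <- list(); cs <- list()
  for (t in seq_along(op$coef)) {
    part <- apply_monomial(st, op$powers[t, ])
    qs[[t]] <- part$quanta
    cs[[t]] <- part$coef * op$coef[t]
  }
  sparse_collect(list(quanta = do.call(rbind, qs), coef = unlist(cs)))
}

# <a|b> for sparse states
sparse_dot <- function(a, b) {
  ka <- apply(a$quanta, 1, paste, collapse = ",")
  kb <- apply(b$quanta, 1, paste, collapse = ",")
  i <- match(ka, kb)
  ok <- !is.na(i)
  sum(a$coef[ok] * b$coef[i[ok]])
}

# <a|Op|b>
op_braket <- function(a, op, b) sparse_dot(a, op_apply(op, b))

# --- operator construction from force fields ------------------------------

# Cubic potential V3 = (1/6) sum_{ijk} f_ijk q_i q_j q_k as unique monomials.
cubic_operator <- function(cubic) {
  M <- dim(cubic)[1]
  coefs <- numeric(0); pows <- list()
  for (i in seq_len(M)) for (j in i:M) for (k in j:M) {
    f <- cubic[i, j, k]
    if (f == 0) next
    nuniq <- length(unique(c(i, j, k)))
    mult <- c(1, 3, 6)[nuniq]           # permutations of the index multiset
    p <- integer(M); p[i] <- p[i] + 1L; p[j] <- p[j] + 1L; p[k] <- p[k] + 1L
    coefs <- c(coefs, f * mult / 6)
    pows[[length(pows) + 1]] <- p
  }
  list(coef = coefs, powers = if (length(pows)) do.call(rbind, pows) else matrix(integer(0), 0, M))
}

# Quartic potential from the semidiagonal store Q[i,j,k] = d4 V/dq_i^2 dq_j dq_k.
# Enumerates unique index multisets {a<=b<=c<=d} with at least two equal
# indices; coefficient is f * (#permutations) / 24.
quartic_operator <- function(quartic) {
  M <- dim(quartic)[1]
  coefs <- numeric(0); pows <- list()
  for (a in seq_len(M)) for (b in a:M) for (c in b:M) for (d in c:M) {
    idx <- c(a, b, c, d)
    tab <- table(idx)
    if (max(tab) < 2) next                      # beyond semidiagonal
    f <- quartic_entry(quartic, idx)
    if (f == 0) next
    mult <- factorial(4) / prod(factorial(tab))
    p <- integer(M)
    for (m in idx) p[m] <- p[m] + 1L
    coefs <- c(coefs, f * mult / 24)
    pows[[length(pows) + 1]] <- p
  }
  list(coef = coefs, powers = if (length(pows)) do.call(rbind, pows) else matrix(integer(0), 0, M))
}

# look up f for an index multiset (>= 2 equal indices) in the semidiagonal store
quartic_entry <- function(quartic, idx) {
  tab <- table(idx)
  dup <- as.integer(names(tab)[which.max(tab)])
  rest <- idx[idx != dup]
  if (length(rest) == 0) return(quartic[dup, dup, dup])          # iiii
  if (length(rest) == 1) return(quartic[dup, dup, rest])         # iiij
  quartic[dup, rest[1], rest[2]]                                 # iijk / iijj
}

# combined anharmonic perturbation operators for a force field
ff_operators <- function(ff) {
  list(V3 = cubic_operator(ff$cubic), V4 = quartic_operator(ff$quartic))
}

# Dipole expansion operators (per Cartesian component comp):
# mu = mu0 + sum d1_i q_i + 1/2 sum d2_ij q_i q_j
#      + (1/6) sum mu3_ijk q^3 (semidiagonal: d3[i,j,] = d3 mu/dq_i^2 dq_j)
dipole_operator <- function(dip, comp, order = c("mu1", "mu2", "mu3")) {
  M <- nrow(dip$d1)
  order <- match.arg(order)
  coefs <- numeric(0); pows <- list()
  add <- function(cf, p) {
    if (cf != 0) {
      coefs <<- c(coefs, cf)
      pows[[length(pows) + 1]] <<- p
    }
  }
  if (order == "mu1") {
    for (i in seq_len(M)) add(dip$d1[i, comp], replace(integer(M), i, 1L))
  } else if (order == "mu2") {
    for (i in seq_len(M)) for (j in i:M) {
      cf <- if (i == j) dip$d2[i, i, comp] / 2 else dip$d2[i, j, comp]
      p <- integer(M); p[i] <- p[i] + 1L; p[j] <- p[j] + 1L
      add(cf, p)
    }
  } else {
    d3 <- dip$d3
    if (is.null(d3)) d3 <- array(0, dim = c(M, M, 3))
    for (i in seq_len(M)) for (j in seq_len(M)) {
      cf <- if (i == j) d3[i, i, comp] / 6 else d3[i, j, comp] / 2
      p <- integer(M); p[i] <- p[i] + 2L; p[j] <- p[j] + 1L
      add(cf, p)
    }
  }
  list(coef = coefs, powers = if (length(pows)) do.call(rbind, pows) else matrix(integer(0), 0, M))
}
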