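#' Resonance-detection thresholds
#'
#' Default acceptance criteria for Fermi and Darling-Dennison resonances.
#' A Fermi candidate \eqn{\omega_i \approx \omega_j + \omega_k} is accepted
#' when the detuning window, the variational depth
#' \eqn{f_{ijk}^4 / (64 (1+\delta_{jk})^2 |\Delta|^3) \ge} \code{fermi_depth}
#' and the perturbation-order ratio
#' \eqn{|f_{ijk} / (8 (1+\delta_{jk}) \Delta)| \ge} \code{fermi_ratio} all
#' pass.  Darling-Dennison candidates require the detuning window, a minimum
#' effective coupling |W| and (for 1-1 and 1-3) a minimum second-order mixing
#' coefficient |W/Delta|.
#'
#' @param fermi_window,fermi_depth,fermi_ratio Fermi criteria (cm^-1, cm^-1,
#'   dimensionless); defaults 200, 1, 0.1.
#' @param dd_window detuning window for all DD kinds, cm^-1 (default 100).
#' @param dd_coupling minimum |W|, cm^-1 (default 10).
#' @param dd11_cmix,dd13_cmix minimum mixing coefficients (defaults 1, 0.3).
#' @return list of class \code{resonance_thresholds}.
#' @export
resonance_thresholds <- function(fermi_window = 200, fermi_depth = 1,
                                 fermi_ratio = 0.1, dd_window = 100,
                                 dd_coupling = 10, dd11_cmix = 1,
                                 dd13_cmix = 0.3) {
  th <- list(fermi_window = fermi_window, fermi_depth = fermi_depth,
             fermi_ratio = fermi_ratio, dd_window = dd_window,
             dd_coupling = dd_coupling, dd11_cmix = dd11_cmix,
             dd13_cmix = dd13_cmix)
  if (any(unlist(th) < 0)) stop("thresholds must be non-negative")
  structure(th, class = "resonance_thresholds")
}

empty_edges <- function() {
  data.frame(kind = character(0), i = integer(0), j = integer(0),
             k = integer(0), l = integer(0), bra = character(0),
             ket = character(0), delta = numeric(0), W = numeric(0),
             depth = numeric(0), ratio = numeric(0), cmix = numeric(0),
             accepted = logical(0), stringsAsFactors = FALSE)
}

# bra/ket quanta vectors of an edge row
edge_states <- function(e, M) {
  bra <- integer(M); ket <- integer(M)
  if (e$kind == "fermi") {
    bra[e$i] <- 1L; ket[e$j] <- ket[e$j] + 1L; ket[e$k] <- ket[e$k] + 1L
  } else if (e$kind == "dd11") {
    bra[e$i] <- 1L; ket[e$j] <- 1L
  } else if (e$kind == "dd13") {
    bra[e$i] <- 1L
    for (m in c(e$j, e$k, e$l)) ket[m] <- ket[m] + 1L
  } else if (e$kind == "dd22") {
    bra[e$i] <- bra[e$i] + 1L; bra[e$j] <- bra[e$j] + 1L
    ket[e$k] <- ket[e$k] + 1L; ket[e$l] <- ket[e$l] + 1L
  } else stop("unknown edge kind")
  list(bra = bra, ket = ket)
}

#' Detect Fermi resonances
#'
#' Scans every cubic triple \eqn{(i, (j, k))}, \eqn{j \le k}, \eqn{i \notin
#' \{j,k\}}, and evaluates the three acceptance criteria (detuning window,
#' variational depth, perturbation ratio).  All diagnostic values are
#' reported, also for rejected candidates.  An exactly degenerate candidate
#' (\eqn{\Delta = 0}) with a nonzero cubic constant is auto-accepted with
#' infinite diagnostics.
#'
#' @param omega harmonic wavenumbers used for the resonance analysis (for
#'   hybrid models, the high-level ones), cm^-1.
#' @param cubic cubic force-constant array, cm^-1.
#' @param th a \code{\link{resonance_thresholds}}.
#' @return edge data frame (one row per candidate with a nonzero constant).
#' @export
detect_fermi <- function(omega, cubic, th = resonance_thresholds()) {
  M <- length(omega)
  rows <- list()
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in j:M) {
    if (i == j || i == k) next
    f <- cubic[i, j, k]
    if (f == 0) next
    delta <- omega[i] - (omega[j] + omega[k])
    dkr <- if (j == k) 1 else 0
    in_window <- abs(delta) <= th$fermi_window
    if (delta == 0) {
      depth <- Inf; ratio <- Inf
      accepted <- in_window
    } else {
      depth <- f^4 / (64 * (1 + dkr)^2 * abs(delta)^3)
      ratio <- abs(f / (8 * (1 + dkr) * delta))
      accepted <- in_window && depth >= th$fermi_depth && ratio >= th$fermi_ratio
    }
    rows[[length(rows) + 1]] <- data.frame(
      kind = "fermi", i = i, j = j, k = k, l = NA_integer_,
      bra = state_label(replace(integer(M), i, 1L)),
      ket = state_label({q <- integer(M); q[j] <- q[j] + 1L; q[k] <- q[k] + 1L; q}),
      delta = delta, W = if (j == k) f / 4 else f / (2 * sqrt(2)),
      depth = depth, ratio = ratio, cmix = NA_real_,
      accepted = accepted, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_edges())
  do.call(rbind, rows)
}

#' Effective coupling between two resonance partners
#'
#' First-order matrix element of the cubic potential for Fermi pairs
#' (\eqn{W = f_{ijk}/(2\sqrt 2)} for a fundamental against a binary
#' combination, \eqn{f_{ijj}/4} against an overtone) and second-order
#' contact-transformation (Van Vleck) matrix elements for Darling-Dennison
#' pairs:
#' \deqn{W_{ab} = \langle a|V_4|b\rangle + \frac{1}{2}\sum_{u \ne a,b}
#'  \langle a|V_3|u\rangle\langle u|V_3|b\rangle
#'  \left[\frac{1}{E_a-E_u} + \frac{1}{E_b-E_u}\right]}
#' Intermediate states whose denominator combination is itself a flagged
#' resonance (or lies within 0.1 cm^-1 of degeneracy) are excluded: they
#' belong inside the variational space, not in the transformation.
#'
#' @param bra,ket quanta vectors of the two states.
#' @param ff an \code{\link{anharmonic_ff}}.
#' @param exclude_keys canonical combination keys of resonances to exclude
#'   from the intermediate sum (usually accepted Fermi edges).
#' @param ops precomputed \code{ff_operators(ff)} (optional).
#' @return coupling W, cm^-1 (symmetric in bra and ket).
#' @export
resonance_coupling <- function(bra, ket, ff, exclude_keys = character(0),
                               ops = NULL) {
  bra <- as.integer(bra); ket <- as.integer(ket)
  omega <- ff$omega
  if (is.null(ops)) ops <- ff_operators(ff)
  sb <- sparse_state(bra)
  w1 <- op_braket(sb, ops$V3, sparse_state(ket)) +
    op_braket(sb, ops$V4, sparse_state(ket))
  ea <- sum(bra * omega); eb <- sum(ket * omega)
  va <- op_apply(ops$V3, sb)
  vb <- op_apply(ops$V3, sparse_state(ket))
  w2 <- 0
  if (length(va$coef) && length(vb$coef)) {
    ka <- apply(va$quanta, 1, paste, collapse = ",")
    kb <- apply(vb$quanta, 1, paste, collapse = ",")
    shared <- intersect(ka, kb)
    for (key in shared) {
      u <- va$quanta[match(key, ka), ]
      if (all(u == bra) || all(u == ket)) next
      eu <- sum(u * omega)
      if (canonical_delta_key(bra - u) %in% exclude_keys) next
      if (canonical_delta_key(ket - u) %in% exclude_keys) next
      if (abs(ea - eu) < 0.1 || abs(eb - eu) < 0.1) next
      w2 <- w2 + va$coef[match(key, ka)] * vb$coef[match(key, kb)] *
        (1 / (ea - eu) + 1 / (eb - eu)) / 2
    }
  }
  w1 + w2
}

#' Detect Darling-Dennison resonances
#'
#' Evaluates 1-1 (fundamental pairs), 2-2 (pairs of 2-quanta states) and 1-3
#' (fundamental against 3-quanta state) candidates against the detuning
#' window, minimum coupling and, where applicable, minimum mixing
#' coefficient.  Couplings are second-order contact-transformation matrix
#' elements (\code{\link{resonance_coupling}}); the mixing coefficient is
#' \eqn{|W/\Delta|} with auto-acceptance at exact degeneracy.
#'
#' @param ff an \code{\link{anharmonic_ff}}.
#' @param kind one of \code{"dd11"}, \code{"dd22"}, \code{"dd13"}.
#' @param th a \code{\link{resonance_thresholds}}.
#' @param omega wavenumbers for the resonance analysis (default those of
#'   \code{ff}; for hybrid models pass the high-level ones).
#' @param exclude_keys flagged combinations excluded from the contact
#'   transformation (accepted Fermi edges).
#' @return edge data frame.
#' @export
detect_dd <- function(ff, kind = c("dd11", "dd22", "dd13"),
                      th = resonance_thresholds(), omega = ff$omega,
                      exclude_keys = character(0)) {
  kind <- match.arg(kind)
  M <- length(omega)
  ops <- ff_operators(ff)
  ffw <- ff; ffw$omega <- omega
  rows <- list()
  push <- function(i, j, k, l, bra, ket) {
    delta <- sum(bra * omega) - sum(ket * omega)
    if (abs(delta) > th$dd_window) {
      W <- NA_real_; cmix <- NA_real_; accepted <- FALSE
    } else {
      W <- resonance_coupling(bra, ket, ffw, exclude_keys, ops)
      cmix <- if (delta == 0) Inf else abs(W / delta)
      accepted <- abs(W) >= th$dd_coupling &&
        (kind == "dd22" ||
           (kind == "dd11" && cmix >= th$dd11_cmix) ||
           (kind == "dd13" && cmix >= th$dd13_cmix))
    }
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, i = i, j = j, k = k, l = l,
      bra = state_label(bra), ket = state_label(ket),
      delta = delta, W = W, depth = NA_real_, ratio = NA_real_,
      cmix = cmix, accepted = accepted, stringsAsFactors = FALSE)
  }
  if (kind == "dd11") {
    if (M > 1) for (i in seq_len(M - 1)) for (j in (i + 1):M) {
      push(i, j, NA_integer_, NA_integer_,
           replace(integer(M), i, 1L), replace(integer(M), j, 1L))
    }
  } else if (kind == "dd22") {
    pairs <- list()
    for (i in seq_len(M)) for (j in i:M) pairs[[length(pairs) + 1]] <- c(i, j)
    if (length(pairs) > 1) for (a in seq_len(length(pairs) - 1)) for (b in (a + 1):length(pairs)) {
      pi_ <- pairs[[a]]; pj <- pairs[[b]]
      bra <- integer(M); bra[pi_[1]] <- bra[pi_[1]] + 1L; bra[pi_[2]] <- bra[pi_[2]] + 1L
      ket <- integer(M); ket[pj[1]] <- ket[pj[1]] + 1L; ket[pj[2]] <- ket[pj[2]] + 1L
      push(pi_[1], pi_[2], pj[1], pj[2], bra, ket)
    }
  } else {
    for (i in seq_len(M)) for (j in seq_len(M)) for (k in j:M) for (l in k:M) {
      ket <- integer(M)
      for (m in c(j, k, l)) ket[m] <- ket[m] + 1L
      push(i, j, k, l, replace(integer(M), i, 1L), ket)
    }
  }
  if (!length(rows)) return(empty_edges())
  do.call(rbind, rows)
}

#' Detect all resonances of a force field
#'
#' Runs Fermi detection, then Darling-Dennison detection of every kind whose
#' states exist at the requested excitation level, excluding accepted Fermi
#' combinations from the contact transformation.
#'
#' @inheritParams detect_dd
#' @param max_quanta maximum total quanta of the state space (2 or 3); 1-3
#'   Darling-Dennison candidates are only evaluated at 3.
#' @return edge data frame with all evaluated candidates; accepted edges form
#'   the resonance registry.
#' @export
detect_resonances <- function(ff, th = resonance_thresholds(),
                              omega = ff$omega, max_quanta = 2) {
  edges <- detect_fermi(omega, ff$cubic, th)
  fermi_keys <- registry_keys(edges, length(omega))
  edges <- rbind(edges, detect_dd(ff, "dd11", th, omega, fermi_keys))
  if (max_quanta >= 2)
    edges <- rbind(edges, detect_dd(ff, "dd22", th, omega, fermi_keys))
  if (max_quanta >= 3)
    edges <- rbind(edges, detect_dd(ff, "dd13", th, omega, fermi_keys))
  edges
}

#' Canonical combination keys of accepted resonance edges
#'
#' Each accepted edge corresponds to a signed combination of harmonic
#' wavenumbers (e.g. \eqn{\omega_i - \omega_j - \omega_k} for a Fermi
#' triple); the keys identify exactly the perturbative terms to remove in
#' deperturbed calculations.
#'
#' @param edges edge data frame.
#' @param M number of modes.
#' @return character vector of canonical keys.
#' @export
registry_keys <- function(edges, M) {
  acc <- edges[edges$accepted, , drop = FALSE]
  if (!nrow(acc)) return(character(0))
  unique(vapply(seq_len(nrow(acc)), function(r) {
    st <- edge_states(acc[r, ], M)
    canonical_delta_key(st$bra - st$ket)
  }, character(1)))
}

# accepted Fermi triples as an (i, j, k) matrix for the chi-matrix removal
fermi_triples <- function(edges) {
  acc <- edges[edges$accepted & edges$kind == "fermi", , drop = FALSE]
  if (!nrow(acc)) return(NULL)
  cbind(acc$i, acc$j, acc$k)
}

#' Group resonance-connected states into polyads
#'
#' Connected components of the accepted-edge graph over the enumerated
#' states (union-find).  States without any accepted edge bypass the
#' variational step.
#'
#' @param states state matrix from \code{\link{enumerate_states}}.
#' @param edges edge data frame (only accepted edges are used).
#' @return list of integer vectors of state row indices (components with at
#'   least two members), with the member edges attached as attribute
#'   \code{"edges"}.
#' @export
build_polyads <- function(states, edges) {
  M <- ncol(states)
  keys <- apply(states, 1, paste, collapse = ",")
  parent <- seq_len(nrow(states))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  acc <- edges[edges$accepted, , drop = FALSE]
  used <- logical(NROW(acc))
  if (nrow(acc)) for (r in seq_len(nrow(acc))) {
    st <- edge_states(acc[r, ], M)
    a <- match(paste(st$bra, collapse = ","), keys)
    b <- match(paste(st$ket, collapse = ","), keys)
    if (is.na(a) || is.na(b)) next       # edge references states outside the window
    used[r] <- TRUE
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nrow(states)), find, integer(1))
  comps <- split(seq_len(nrow(states)), roots)
  comps <- comps[vapply(comps, length, integer(1)) > 1]
  names(comps) <- NULL
  lapply(comps, function(members) {
    structure(members, edges = acc[used & vapply(seq_len(nrow(acc)), function(r) {
      st <- edge_states(acc[r, ], M)
      a <- match(paste(st$bra, collapse = ","), keys)
      b <- match(paste(st$ket, collapse = ","), keys)
      !is.na(a) && !is.na(b) && a %in% members && b %in% members
    }, logical(1)), , drop = FALSE])
  })
}

#' Variational correction of one polyad
#'
#' Builds the symmetric variational matrix (deperturbed energies on the
#' diagonal, couplings W of accepted edges off-diagonal, zero elsewhere),
#' diagonalizes it, and projects the deperturbed transition moments onto the
#' eigenstates: \eqn{\mu_s = \sum_v c_{v,s}\, \mu_v}.  Eigenvector phases
#' are fixed by making the largest-magnitude coefficient positive (ties by
#' lowest member index).
#'
#' @param members state row indices of the polyad.
#' @param states state matrix.
#' @param edges accepted edges among the members (attribute set by
#'   \code{\link{build_polyads}}).
#' @param energies deperturbed transition energies of all states, cm^-1.
#' @param moments named list (per flavor) of n_states x 3 moment matrices.
#' @return list with \code{energies}, \code{vectors}, \code{matrix},
#'   \code{members}, \code{moments} (projected, per flavor).
#' @export
variational_correct <- function(members, states, edges, energies, moments) {
  M <- ncol(states)
  n <- length(members)
  keys <- apply(states[members, , drop = FALSE], 1, paste, collapse = ",")
  H <- diag(energies[members], n)
  labs <- apply(states[members, , drop = FALSE], 1, state_label)
  dimnames(H) <- list(labs, labs)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    st <- edge_states(edges[r, ], M)
    a <- match(paste(st$bra, collapse = ","), keys)
    b <- match(paste(st$ket, collapse = ","), keys)
    if (is.na(a) || is.na(b)) next
    H[a, b] <- H[b, a] <- edges$W[r]
  }
  if (max(abs(H - t(H))) > 0) stop("polyad matrix is not symmetric (construction bug)")
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  for (s in seq_len(n)) {            # reproducible phases
    c_ <- vecs[, s]
    lead <- which(abs(c_) == max(abs(c_)))[1]
    if (c_[lead] < 0) vecs[, s] <- -c_
  }
  proj <- lapply(moments, function(mm) crossprod(vecs, mm[members, , drop = FALSE]))
  list(members = members, matrix = H, energies = vals, vectors = vecs,
       moments = proj,
       moments_in = lapply(moments, function(mm) mm[members, , drop = FALSE]))
}

#' Composition string of a corrected state
#'
#' Formats the eigenvector of a variationally corrected state as a sum of
#' harmonic-labelled kets, keeping coefficients with \eqn{|c| \ge}
#' \code{c_min}, sorted by decreasing magnitude, the leading sign normalized
#' positive, e.g. \code{"0.953 |7^1>"}.
#'
#' @param coefficients eigenvector entries.
#' @param labels state labels of the polyad members.
#' @param c_min printing threshold (default 0.2; smaller coefficients are
#'   retained in the data, only omitted from the string).
#' @return character scalar.
#' @export
describe_polyad <- function(coefficients, labels, c_min = 0.2) {
  ord <- order(-abs(coefficients))
  c_ <- coefficients[ord]; lab <- labels[ord]
  if (length(c_) && c_[1] < 0) c_ <- -c_
  keep <- abs(c_) >= c_min
  if (!any(keep)) keep[1] <- TRUE
  c_ <- c_[keep]; lab <- lab[keep]
  out <- sprintf("%.3f |%s>", abs(c_), lab)
  signs <- ifelse(c_ >= 0, " + ", " - ")
  paste0(out[1], if (length(out) > 1)
    paste0(paste0(signs[-1], out[-1]), collapse = "") else "")
}
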