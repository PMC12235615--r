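#' Duschinsky overlap between two normal-mode bases
#'
#' The overlap matrix \eqn{J = L_\mathrm{high}^T L_\mathrm{low}} between the
#' mass-weighted mode vectors of two electronic-structure levels measures
#' how similar their normal coordinates are; \eqn{J_{ik}^2 \ge 0.9} is the
#' acceptance value used to treat two coordinates as identical.  Both bases
#' must refer to the same atoms in the same order at (numerically) the same
#' geometry; axis switching between different optimized geometries is not
#' handled.
#'
#' @param high,low \code{\link{normal_mode_basis}} objects.
#' @param geom_tol maximum allowed geometry RMSD, Angstrom.
#' @return M x M matrix of class \code{duschinsky_map}.
#' @export
duschinsky_matrix <- function(high, low, geom_tol = 1e-3) {
  stopifnot(inherits(high, "normal_mode_basis"), inherits(low, "normal_mode_basis"))
  if (high$n_atoms != low$n_atoms) stop("atom-count mismatch between levels")
  if (length(high$omega) != length(low$omega)) stop("mode-count mismatch between levels")
  if (max(abs(high$masses - low$masses)) > 1e-8) stop("atomic masses differ between levels")
  rmsd <- sqrt(mean((high$geometry - low$geometry)^2))
  if (rmsd > geom_tol)
    stop(sprintf("geometry RMSD %.3g Angstrom exceeds tolerance %.3g (axis switching not handled)",
                 rmsd, geom_tol))
  J <- crossprod(high$L, low$L)
  structure(J, class = c("duschinsky_map", "matrix"))
}

#' Match modes across levels by squared Duschinsky overlap
#'
#' Greedy assignment by descending \eqn{J_{ik}^2} (ties broken by lower mode
#' index), signs chosen so matched overlaps are positive.  Any mode whose
#' best remaining overlap falls below \code{threshold} makes the merge
#' undefined and is a hard error listing the mode and its best overlap.
#'
#' @param J a \code{\link{duschinsky_matrix}} result (square).
#' @param threshold squared-overlap acceptance value (default 0.9).
#' @return list of class \code{mode_mapping}: \code{permutation} (high mode
#'   i is matched to low mode \code{permutation[i]}), \code{signs},
#'   \code{j2} (squared overlap per accepted pair).
#' @export
match_modes <- function(J, threshold = 0.9) {
  M <- nrow(J)
  if (ncol(J) != M) stop("J must be square")
  J2 <- J^2
  perm <- integer(M); signs <- integer(M); j2 <- numeric(M)
  free_h <- rep(TRUE, M); free_l <- rep(TRUE, M)
  for (step in seq_len(M)) {
    best <- -1; bi <- 0; bk <- 0
    for (i in which(free_h)) for (k in which(free_l)) {
      if (J2[i, k] > best + 1e-15) { best <- J2[i, k]; bi <- i; bk <- k }
    }
    if (best < threshold) {
      bad <- which(free_h)
      stop(sprintf("unmatched modes (J^2 below %.3g): %s; best overlaps %s",
                   threshold, paste(bad, collapse = ", "),
                   paste(signif(apply(J2[bad, , drop = FALSE], 1, max), 4),
                         collapse = ", ")))
    }
    perm[bi] <- bk; signs[bi] <- if (J[bi, bk] >= 0) 1L else -1L
    j2[bi] <- best
    free_h[bi] <- FALSE; free_l[bk] <- FALSE
  }
  structure(list(permutation = perm, signs = signs, j2 = j2,
                 threshold = threshold), class = "mode_mapping")
}

#' @export
print.mode_mapping <- function(x, ...) {
  cat("<mode_mapping> high -> low (sign, J^2):\n")
  for (i in seq_along(x$permutation))
    cat(sprintf("  %3d -> %3d  (%+d, %.4f)\n", i, x$permutation[i],
                x$signs[i], x$j2[i]))
  invisible(x)
}

#' Merge a high-level harmonic model with a low-level anharmonic field
#'
#' Builds one of the three hybrid QM1/QM2 models:
#' \describe{
#'   \item{\code{"freq"}}{high-level harmonic wavenumbers replace the
#'     low-level ones, everything else untouched (the typical
#'     literature-frequencies case; no tensor remapping is performed, and a
#'     warning is emitted when the energy-order pairing is ambiguous).}
#'   \item{\code{"pes"}}{high-level wavenumbers and normal coordinates are
#'     adopted; the low-level cubic/quartic tensors are re-indexed through
#'     the Duschinsky mode mapping and re-signed (odd-order tensors pick up
#'     the product of the signs of their indices).  The low-level dipole
#'     surface is remapped the same way.}
#'   \item{\code{"pes+ps"}}{as \code{"pes"}, plus the high-level dipole
#'     first derivatives replace the remapped low-level ones.}
#' }
#' In every scheme the high-level harmonic wavenumbers are the ones carried
#' into the VPT2 formulas and the resonance analysis.
#'
#' @param high list with elements \code{basis} and (for \code{"pes+ps"})
#'   \code{dip} carrying at least the dipole first derivatives.
#' @param low list with elements \code{basis}, \code{ff}, \code{dip}.
#' @param scheme \code{"freq"}, \code{"pes"} or \code{"pes+ps"}.
#' @param threshold squared-overlap acceptance for mode matching.
#' @return list with elements \code{basis}, \code{ff}, \code{dip} and
#'   \code{mapping} (NULL for \code{"freq"}).
#' @export
hybrid_merge <- function(high, low, scheme = c("freq", "pes", "pes+ps"),
                         threshold = 0.9) {
  scheme <- match.arg(scheme)
  M <- length(low$basis$omega)
  if (length(high$basis$omega) != M) stop("mode-count mismatch between levels")
  if (scheme == "freq") {
    if (is.unsorted(rev(high$basis$omega)) || is.unsorted(rev(low$basis$omega)))
      warning("energy-order pairing of modes is ambiguous for scheme 'freq' (non-monotonic omega)")
    basis <- low$basis
    basis$omega <- high$basis$omega
    ff <- low$ff
    ff$omega <- high$basis$omega
    return(list(basis = basis, ff = ff, dip = low$dip, mapping = NULL))
  }
  J <- duschinsky_matrix(high$basis, low$basis)
  map <- match_modes(J, threshold)
  p <- map$permutation; s <- map$signs
  cubic <- array(0, dim = c(M, M, M))
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M))
    cubic[i, j, k] <- s[i] * s[j] * s[k] * low$ff$cubic[p[i], p[j], p[k]]
  quartic <- array(0, dim = c(M, M, M))
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in seq_len(M))
    quartic[i, j, k] <- s[j] * s[k] * low$ff$quartic[p[i], p[j], p[k]]
  d1 <- low$dip$d1[p, , drop = FALSE] * s
  d2 <- array(0, dim = c(M, M, 3)); d3 <- array(0, dim = c(M, M, 3))
  for (i in seq_len(M)) for (j in seq_len(M)) {
    d2[i, j, ] <- s[i] * s[j] * low$dip$d2[p[i], p[j], ]
    d3[i, j, ] <- s[j] * low$dip$d3[p[i], p[j], ]
  }
  if (scheme == "pes+ps") {
    if (is.null(high$dip)) stop("scheme 'pes+ps' needs the high-level dipole first derivatives")
    d1 <- high$dip$d1
  }
  ff <- anharmonic_ff(high$basis$omega, cubic, quartic,
                      level_tag = paste0(high$basis$level_tag, "//", low$ff$level_tag),
                      step = low$ff$step)
  dip <- dipole_surface(mu0 = low$dip$mu0, d1 = d1, d2 = d2, d3 = d3)
  list(basis = high$basis, ff = ff, dip = dip, mapping = map)
}
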