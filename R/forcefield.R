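#' Harmonic normal-mode basis
#'
#' Container for the harmonic description of a molecule: atomic masses,
#' Cartesian geometry, mass-weighted normal-mode vectors and harmonic
#' wavenumbers.  Modes are stored in spectroscopic order (grouped by
#' irreducible representation, decreasing wavenumber within a group; without
#' irrep labels, one block sorted by decreasing wavenumber).
#'
#' @param masses atomic masses, u (length n_atoms).
#' @param geometry Cartesian geometry, Angstrom (n_atoms x 3 matrix).
#' @param L mass-weighted Cartesian displacement matrix, 3*n_atoms rows by M
#'   columns with orthonormal columns.
#' @param omega harmonic wavenumbers, cm^-1 (length M, all > 0).
#' @param irrep optional character vector of symmetry labels per mode.
#' @param level_tag free-text provenance of the electronic-structure level.
#' @return object of class \code{normal_mode_basis}.
#' @export
normal_mode_basis <- function(masses, geometry, L, omega, irrep = NULL,
                              level_tag = "unspecified") {
  geometry <- as.matrix(geometry)
  L <- as.matrix(L)
  n <- length(masses)
  M <- length(omega)
  if (nrow(geometry) != n || ncol(geometry) != 3)
    stop("geometry must be n_atoms x 3")
  if (nrow(L) != 3 * n || ncol(L) != M)
    stop("L must be 3*n_atoms x M")
  g <- crossprod(L) - diag(M)
  if (max(abs(g)) > 1e-8)
    stop(sprintf("columns of L are not orthonormal (max deviation %.3g)", max(abs(g))))
  if (any(omega <= 0)) stop("harmonic wavenumbers must be strictly positive")
  if (!is.null(irrep) && length(irrep) != M) stop("irrep must have one label per mode")
  check_spectroscopic_order(omega, irrep)
  structure(list(n_atoms = n, masses = as.numeric(masses), geometry = geometry,
                 L = L, omega = as.numeric(omega), irrep = irrep,
                 level_tag = level_tag),
            class = "normal_mode_basis")
}

check_spectroscopic_order <- function(omega, irrep) {
  blocks <- if (is.null(irrep)) list(seq_along(omega)) else split(seq_along(omega), factor(irrep, levels = unique(irrep)))
  for (b in blocks) {
    if (is.unsorted(rev(omega[b]), strictly = FALSE))
      warning("modes are not in spectroscopic order (decreasing omega within a symmetry block)")
  }
  invisible(TRUE)
}

#' Anharmonic force field in dimensionless normal coordinates
#'
#' Cubic and semidiagonal quartic force constants, cm^-1, with respect to
#' dimensionless normal coordinates q.  The cubic tensor is stored in full
#' and must be totally symmetric; the quartic constants are stored as
#' \code{quartic[i, j, k]} = \eqn{\partial^4 V/\partial q_i^2 \partial q_j
#' \partial q_k} (covers every entry with at least two equal indices),
#' symmetric in (j, k) and consistent across equivalent slots
#' (\code{quartic[i,j,j] == quartic[j,i,i]}).
#'
#' @param omega harmonic wavenumbers, cm^-1 (the copy used in the VPT2
#'   formulas).
#' @param cubic M x M x M array, cm^-1.
#' @param quartic M x M x M semidiagonal array, cm^-1 (see Details).
#' @param level_tag,step metadata: provenance and differentiation step.
#' @return object of class \code{anharmonic_ff}.
#' @export
anharmonic_ff <- function(omega, cubic, quartic, level_tag = "unspecified",
                          step = NA_real_) {
  M <- length(omega)
  if (!all(dim(cubic) == M) || !all(dim(quartic) == M))
    stop("tensor dimensions do not match the number of modes")
  cubic <- symmetrize_cubic(cubic, tol_error = 1e-3)
  quartic <- symmetrize_quartic(quartic, tol_error = 1e-3)
  structure(list(omega = as.numeric(omega), cubic = cubic, quartic = quartic,
                 level_tag = level_tag, step = step),
            class = "anharmonic_ff")
}

# Symmetrize a cubic tensor over index permutations; error above tol_error,
# warn on any measurable asymmetry below it.  The maximum deviation is kept
# as attribute "max_asymmetry".
symmetrize_cubic <- function(cubic, tol_error = 1e-3, tol_warn = 1e-9) {
  M <- dim(cubic)[1]
  out <- cubic
  worst <- 0; worst_idx <- NULL
  for (i in seq_len(M)) for (j in i:M) for (k in j:M) {
    perms <- unique(t(apply(perms3(), 1, function(p) c(i, j, k)[p])))
    vals <- apply(perms, 1, function(ix) cubic[ix[1], ix[2], ix[3]])
    spread <- max(vals) - min(vals)
    if (spread > worst) { worst <- spread; worst_idx <- c(i, j, k) }
    if (spread > tol_error)
      stop(sprintf("cubic tensor asymmetric at (%d,%d,%d): spread %.3g cm^-1 exceeds %.3g",
                   i, j, k, spread, tol_error))
    m <- mean(vals)
    for (r in seq_len(nrow(perms))) out[perms[r, 1], perms[r, 2], perms[r, 3]] <- m
  }
  if (worst > tol_warn)
    warning(sprintf("cubic tensor symmetrized; max asymmetry %.3g cm^-1 at (%d,%d,%d)",
                    worst, worst_idx[1], worst_idx[2], worst_idx[3]))
  attr(out, "max_asymmetry") <- worst
  out
}

perms3 <- function() rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))

# Symmetrize the semidiagonal quartic store: (j,k) exchange within a slice
# and consistency of the doubly-paired entries quartic[i,j,j] == quartic[j,i,i].
symmetrize_quartic <- function(quartic, tol_error = 1e-3, tol_warn = 1e-9) {
  M <- dim(quartic)[1]
  out <- quartic
  worst <- 0; worst_idx <- NULL
  for (i in seq_len(M)) for (j in seq_len(M)) for (k in j:M) {
    vals <- c(quartic[i, j, k], quartic[i, k, j])
    if (j != i && k == j) vals <- c(vals, quartic[j, i, i], quartic[j, i, i])
    spread <- max(vals) - min(vals)
    if (spread > worst) { worst <- spread; worst_idx <- c(i, i, j, k) }
    if (spread > tol_error)
      stop(sprintf("quartic store asymmetric at (%d,%d,%d,%d): spread %.3g cm^-1",
                   i, i, j, k, spread))
    m <- mean(vals)
    out[i, j, k] <- m; out[i, k, j] <- m
    if (j != i && k == j) out[j, i, i] <- m
  }
  if (worst > tol_warn)
    warning(sprintf("quartic store symmetrized; max asymmetry %.3g cm^-1", worst))
  attr(out, "max_asymmetry") <- worst
  out
}

#' Dipole-moment surface in dimensionless normal coordinates
#'
#' Equilibrium dipole and its derivatives with respect to dimensionless
#' normal coordinates, in debye.  Third derivatives are semidiagonal:
#' \code{d3[i, j, ]} = \eqn{\partial^3\mu/\partial q_i^2\partial q_j}.
#'
#' @param mu0 equilibrium dipole, debye (length 3).
#' @param d1 first derivatives, M x 3.
#' @param d2 second derivatives, M x M x 3, symmetric in (i, j).
#' @param d3 semidiagonal third derivatives, M x M x 3 (may be NULL for a
#'   surface truncated at second order).
#' @return object of class \code{dipole_surface}.
#' @export
dipole_surface <- function(mu0 = c(0, 0, 0), d1, d2 = NULL, d3 = NULL) {
  d1 <- as.matrix(d1)
  M <- nrow(d1)
  if (ncol(d1) != 3) stop("d1 must be M x 3")
  if (is.null(d2)) d2 <- array(0, dim = c(M, M, 3))
  if (is.null(d3)) d3 <- array(0, dim = c(M, M, 3))
  for (c_ in 1:3) {
    s <- d2[, , c_]
    if (max(abs(s - t(s))) > 1e-8)
      stop("dipole second derivatives not symmetric in (i, j)")
    d2[, , c_] <- (s + t(s)) / 2
  }
  structure(list(mu0 = as.numeric(mu0), d1 = d1, d2 = d2, d3 = d3),
            class = "dipole_surface")
}

#' @export
print.normal_mode_basis <- function(x, ...) {
  cat("<normal_mode_basis> ", length(x$omega), " modes, ", x$n_atoms,
      " atoms  [", x$level_tag, "]\n", sep = "")
  cat("  omega (cm^-1):", paste(signif(x$omega, 6), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.anharmonic_ff <- function(x, ...) {
  cat("<anharmonic_ff> ", length(x$omega), " modes  [", x$level_tag, "]\n", sep = "")
  cat("  max |cubic| =", signif(max(abs(x$cubic)), 4),
      " max |quartic| =", signif(max(abs(x$quartic)), 4), "cm^-1\n")
  invisible(x)
}

#' @export
print.dipole_surface <- function(x, ...) {
  cat("<dipole_surface> ", nrow(x$d1), " modes; |mu0| = ",
      signif(sqrt(sum(x$mu0^2)), 4), " D\n", sep = "")
  invisible(x)
}
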