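# The AFF ("anharmonic force field") plain-text exchange format.
#
# Versioned, line-oriented, 1-based mode indices, cm^-1 and debye units,
# full double precision on write.  Sections:
#   [meta]     version / modes / atoms / level_tag / step
#   [atoms]    mass x y z                  (u, Angstrom)
#   [modes]    one row per Cartesian component, M columns (mass-weighted L)
#   [omega]    harmonic wavenumbers, one per line
#   [irrep]    optional symmetry label per mode
#   [cubic]    i j k value                 (any permutation; checked)
#   [quartic]  i j k l value               (>= 2 equal indices)
#   [dipole0]  mu_x mu_y mu_z
#   [dipole1]  i dx dy dz
#   [dipole2]  i j dx dy dz
#   [dipole3]  i j dx dy dz                (d3 mu / dq_i^2 dq_j)

fmt_full <- function(x) formatC(x, digits = 17, format = "e")

#' Write an AFF file
#'
#' Serializes a basis / force-field / dipole-surface triple into the
#' plain-text AFF format at full double precision (round-trips
#' bit-identically through \code{\link{read_aff}}).  Unique tensor entries
#' only (sorted indices).
#'
#' @param basis a \code{\link{normal_mode_basis}}.
#' @param ff an \code{\link{anharmonic_ff}}.
#' @param dip a \code{\link{dipole_surface}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_aff <- function(basis, ff, dip, path) {
  M <- length(basis$omega)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("[meta]")
  w("version 1")
  w("modes ", M)
  w("atoms ", basis$n_atoms)
  w("level_tag ", basis$level_tag)
  if (!is.na(ff$step)) w("step ", fmt_full(ff$step))
  w("[atoms]")
  for (a in seq_len(basis$n_atoms))
    w(paste(fmt_full(c(basis$masses[a], basis$geometry[a, ])), collapse = " "))
  w("[modes]")
  for (r in seq_len(nrow(basis$L)))
    w(paste(fmt_full(basis$L[r, ]), collapse = " "))
  w("[omega]")
  for (m in seq_len(M)) w(fmt_full(basis$omega[m]))
  if (!is.null(basis$irrep)) {
    w("[irrep]")
    for (m in seq_len(M)) w(basis$irrep[m])
  }
  w("[cubic]")
  for (i in seq_len(M)) for (j in i:M) for (k in j:M) {
    if (ff$cubic[i, j, k] != 0)
      w(i, " ", j, " ", k, " ", fmt_full(ff$cubic[i, j, k]))
  }
  w("[quartic]")
  for (i in seq_len(M)) for (j in i:M) for (k in j:M) for (l in k:M) {
    idx <- c(i, j, k, l)
    if (max(table(idx)) < 2) next
    v <- quartic_entry(ff$quartic, idx)
    if (v != 0) w(paste(idx, collapse = " "), " ", fmt_full(v))
  }
  w("[dipole0]")
  w(paste(fmt_full(dip$mu0), collapse = " "))
  w("[dipole1]")
  for (i in seq_len(M)) w(i, " ", paste(fmt_full(dip$d1[i, ]), collapse = " "))
  w("[dipole2]")
  for (i in seq_len(M)) for (j in i:M) {
    v <- dip$d2[i, j, ]
    if (any(v != 0)) w(i, " ", j, " ", paste(fmt_full(v), collapse = " "))
  }
  w("[dipole3]")
  for (i in seq_len(M)) for (j in seq_len(M)) {
    v <- dip$d3[i, j, ]
    if (any(v != 0)) w(i, " ", j, " ", paste(fmt_full(v), collapse = " "))
  }
  invisible(path)
}

#' Read an AFF file
#'
#' Parses and validates an AFF file: all container invariants are enforced
#' (orthonormal modes, positive wavenumbers, tensor symmetry).  Redundant
#' permuted tensor entries are cross-checked; a spread above 1e-3 cm^-1 for
#' the same index multiset is a validation error naming the indices, smaller
#' spreads are averaged with a warning.
#'
#' @param path AFF file path.
#' @return list with elements \code{basis}, \code{ff}, \code{dip}.
#' @export
read_aff <- function(path) {
  if (!file.exists(path)) stop("AFF file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec_at <- grep("^\\[.*\\]$", lines)
  if (!length(sec_at) || sec_at[1] != 1) stop("AFF parse error: file must start with [meta]")
  sec_names <- gsub("^\\[|\\]$", "", lines[sec_at])
  sections <- list()
  for (s in seq_along(sec_at)) {
    from <- sec_at[s] + 1
    to <- if (s < length(sec_at)) sec_at[s + 1] - 1 else length(lines)
    sections[[sec_names[s]]] <- if (from > to) character(0) else lines[from:to]
  }
  need <- c("meta", "atoms", "modes", "omega", "cubic", "quartic", "dipole1")
  for (s in need) if (!s %in% names(sections))
    stop("AFF parse error: missing section [", s, "]")

  meta <- strsplit(sections$meta, "\\s+")
  meta <- stats::setNames(vapply(meta, function(x) paste(x[-1], collapse = " "),
                                 character(1)),
                          vapply(meta, `[`, character(1), 1))
  if (!"version" %in% names(meta)) stop("AFF parse error: [meta] must declare version")
  if (!"modes" %in% names(meta)) stop("AFF parse error: [meta] must declare modes")
  M <- as.integer(meta[["modes"]])
  n_atoms <- as.integer(meta[["atoms"]])
  step <- if ("step" %in% names(meta)) as.numeric(meta[["step"]]) else NA_real_

  num_rows <- function(sec) {
    if (!length(sections[[sec]])) return(matrix(numeric(0), 0, 0))
    do.call(rbind, lapply(strsplit(sections[[sec]], "\\s+"), as.numeric))
  }
  atoms <- num_rows("atoms")
  if (nrow(atoms) != n_atoms || ncol(atoms) != 4)
    stop("AFF parse error: [atoms] must have n_atoms rows of 'mass x y z'")
  L <- num_rows("modes")
  if (nrow(L) != 3 * n_atoms || ncol(L) != M)
    stop("AFF parse error: [modes] must be 3*atoms rows by modes columns")
  omega <- as.numeric(sections$omega)
  if (length(omega) != M) stop("AFF parse error: [omega] must list one wavenumber per mode")
  irrep <- if ("irrep" %in% names(sections)) sections$irrep else NULL

  cubic <- read_cubic_entries(num_rows("cubic"), M)
  quartic <- read_quartic_entries(num_rows("quartic"), M)

  mu0 <- if ("dipole0" %in% names(sections)) as.numeric(strsplit(sections$dipole0, "\\s+")[[1]]) else c(0, 0, 0)
  d1r <- num_rows("dipole1")
  if (nrow(d1r) != M || ncol(d1r) != 4)
    stop("AFF parse error: [dipole1] must have one 'i dx dy dz' row per mode")
  d1 <- matrix(0, M, 3); d1[d1r[, 1], ] <- d1r[, 2:4]
  d2 <- array(0, dim = c(M, M, 3))
  if ("dipole2" %in% names(sections)) {
    rows <- num_rows("dipole2")
    if (nrow(rows)) for (r in seq_len(nrow(rows))) {
      i <- rows[r, 1]; j <- rows[r, 2]; v <- rows[r, 3:5]
      if (any(d2[j, i, ] != 0) && max(abs(d2[j, i, ] - v)) > 1e-8)
        stop(sprintf("AFF validation error: dipole2 entries (%d,%d) and (%d,%d) disagree", i, j, j, i))
      d2[i, j, ] <- d2[j, i, ] <- v
    }
  }
  d3 <- array(0, dim = c(M, M, 3))
  if ("dipole3" %in% names(sections)) {
    rows <- num_rows("dipole3")
    if (nrow(rows)) for (r in seq_len(nrow(rows))) d3[rows[r, 1], rows[r, 2], ] <- rows[r, 3:5]
  }

  basis <- normal_mode_basis(atoms[, 1], atoms[, 2:4, drop = FALSE], L, omega,
                             irrep = irrep,
                             level_tag = if ("level_tag" %in% names(meta)) meta[["level_tag"]] else "unspecified")
  ff <- anharmonic_ff(omega, cubic, quartic,
                      level_tag = basis$level_tag, step = step)
  dip <- dipole_surface(mu0 = mu0, d1 = d1, d2 = d2, d3 = d3)
  list(basis = basis, ff = ff, dip = dip)
}

# accumulate possibly redundant cubic records, cross-checking permutations
read_cubic_entries <- function(rows, M, tol = 1e-3) {
  cubic <- array(0, dim = c(M, M, M))
  if (!nrow(rows)) return(cubic)
  if (ncol(rows) != 4) stop("AFF parse error: [cubic] rows must be 'i j k value'")
  key <- apply(rows[, 1:3, drop = FALSE], 1, function(ix) paste(sort(ix), collapse = ","))
  for (kk in unique(key)) {
    vals <- rows[key == kk, 4]
    spread <- max(vals) - min(vals)
    ix <- as.integer(strsplit(kk, ",")[[1]])
    if (spread > tol)
      stop(sprintf("AFF validation error: cubic symmetry violation at (%d,%d,%d), spread %.3g cm^-1",
                   ix[1], ix[2], ix[3], spread))
    if (spread > 1e-9)
      warning(sprintf("cubic entries for (%d,%d,%d) averaged (spread %.3g cm^-1)",
                      ix[1], ix[2], ix[3], spread))
    v <- mean(vals)
    for (p in seq_len(nrow(perms3()))) {
      jx <- ix[perms3()[p, ]]
      cubic[jx[1], jx[2], jx[3]] <- v
    }
  }
  cubic
}

read_quartic_entries <- function(rows, M, tol = 1e-3) {
  quartic <- array(0, dim = c(M, M, M))
  if (!nrow(rows)) return(quartic)
  if (ncol(rows) != 5) stop("AFF parse error: [quartic] rows must be 'i j k l value'")
  key <- apply(rows[, 1:4, drop = FALSE], 1, function(ix) paste(sort(ix), collapse = ","))
  for (kk in unique(key)) {
    ix <- as.integer(strsplit(kk, ",")[[1]])
    if (max(table(ix)) < 2)
      stop(sprintf("AFF validation error: quartic entry (%s) has no repeated index (beyond semidiagonal)",
                   paste(ix, collapse = ",")))
    vals <- rows[key == kk, 5]
    spread <- max(vals) - min(vals)
    if (spread > tol)
      stop(sprintf("AFF validation error: quartic symmetry violation at (%s), spread %.3g cm^-1",
                   paste(ix, collapse = ","), spread))
    v <- mean(vals)
    tab <- table(ix)
    dup <- as.integer(names(tab)[which.max(tab)])
    rest <- ix[ix != dup]
    if (length(rest) == 0) quartic[dup, dup, dup] <- v
    else if (length(rest) == 1) quartic[dup, dup, rest] <- quartic[dup, rest, dup] <- v
    else {
      quartic[dup, rest[1], rest[2]] <- quartic[dup, rest[2], rest[1]] <- v
      if (rest[1] == rest[2] && rest[1] != dup) quartic[rest[1], dup, dup] <- v
    }
  }
  quartic
}

#' Assemble anharmonic constants from displaced Hessians by finite differences
#'
#' Given Hessians and dipole gradients (already in reduced normal-coordinate
#' units, cm^-1 and debye) evaluated at \eqn{\pm\delta} displacements along
#' each mode plus the undisplaced reference, forms
#' \deqn{f_{ijk} = [H_{jk}(+\delta_i) - H_{jk}(-\delta_i)]/(2\delta)}
#' \deqn{f_{iijk} = [H_{jk}(+\delta_i) - 2 H_{jk}(0) + H_{jk}(-\delta_i)]/\delta^2}
#' and analogously the dipole second and semidiagonal third derivatives from
#' the dipole gradients.  All permutation-equivalent estimates of the same
#' constant are averaged; the largest spread is attached as attribute
#' \code{"fd_spread"} on each returned tensor.  Central differences are
#' exact (to round-off) on potentials that are polynomials of degree at most
#' four, for any step.
#'
#' @param disp list with elements \code{step} (dimensionless displacement,
#'   > 0), \code{hess0} (M x M), \code{hess_plus}, \code{hess_minus} (lists
#'   of M Hessians), \code{dgrad0} (M x 3), \code{dgrad_plus},
#'   \code{dgrad_minus} (lists of M dipole gradients), optional \code{mu0},
#'   \code{omega} (reference wavenumbers; default \code{diag(hess0)}) and
#'   \code{level_tag}.
#' @return list with elements \code{ff} and \code{dip}.
#' @export
aff_from_displacements <- function(disp) {
  step <- disp$step
  if (is.null(step) || step <= 0) stop("displacement step must be positive")
  M <- nrow(disp$hess0)
  for (i in seq_len(M)) {
    if (is.null(disp$hess_plus[[i]])) stop("missing displacement: mode ", i, ", sign +")
    if (is.null(disp$hess_minus[[i]])) stop("missing displacement: mode ", i, ", sign -")
  }
  omega <- if (!is.null(disp$omega)) disp$omega else diag(disp$hess0)

  # cubic: one estimate per displaced mode; average over the multiset
  est <- list(); spread_max <- 0
  acc <- function(key, v) est[[key]] <<- c(est[[key]], v)
  for (i in seq_len(M)) {
    D <- (disp$hess_plus[[i]] - disp$hess_minus[[i]]) / (2 * step)
    for (j in seq_len(M)) for (k in j:M)
      acc(paste(sort(c(i, j, k)), collapse = ","), D[j, k])
  }
  cubic <- array(0, dim = c(M, M, M))
  for (kk in names(est)) {
    vals <- est[[kk]]
    spread_max <- max(spread_max, max(vals) - min(vals))
    ix <- as.integer(strsplit(kk, ",")[[1]])
    v <- mean(vals)
    for (p in seq_len(nrow(perms3()))) {
      jx <- ix[perms3()[p, ]]
      cubic[jx[1], jx[2], jx[3]] <- v
    }
  }

  est <- list()
  for (i in seq_len(M)) {
    D2 <- (disp$hess_plus[[i]] - 2 * disp$hess0 + disp$hess_minus[[i]]) / step^2
    for (j in seq_len(M)) for (k in j:M)
      acc(paste0(i, "|", j, ",", k), D2[j, k])
  }
  # merge equivalent quartic slots (i|j,j equals j|i,i)
  quartic <- array(0, dim = c(M, M, M))
  qspread <- 0
  done <- character(0)
  for (kk in names(est)) {
    parts <- strsplit(kk, "\\|")[[1]]
    i <- as.integer(parts[1]); jk <- as.integer(strsplit(parts[2], ",")[[1]])
    canon <- paste(sort(c(i, i, jk)), collapse = ",")
    if (canon %in% done) next
    done <- c(done, canon)
    vals <- est[[kk]]
    if (jk[1] == jk[2] && jk[1] != i) {
      alt <- paste(jk[1], "|", paste(sort(c(i, i)), collapse = ","), sep = "")
      if (!is.null(est[[alt]])) vals <- c(vals, est[[alt]])
    }
    qspread <- max(qspread, max(vals) - min(vals))
    v <- mean(vals)
    quartic[i, jk[1], jk[2]] <- quartic[i, jk[2], jk[1]] <- v
    if (jk[1] == jk[2] && jk[1] != i) quartic[jk[1], i, i] <- v
  }

  # dipole derivatives from dipole gradients
  d2 <- array(0, dim = c(M, M, 3)); d3 <- array(0, dim = c(M, M, 3))
  dspread <- 0
  if (!is.null(disp$dgrad0)) {
    for (i in seq_len(M)) {
      if (is.null(disp$dgrad_plus[[i]])) stop("missing dipole displacement: mode ", i, ", sign +")
      if (is.null(disp$dgrad_minus[[i]])) stop("missing dipole displacement: mode ", i, ", sign -")
    }
    raw <- array(0, dim = c(M, M, 3))
    for (i in seq_len(M))
      raw[i, , ] <- (disp$dgrad_plus[[i]] - disp$dgrad_minus[[i]]) / (2 * step)
    for (i in seq_len(M)) for (j in i:M) {
      pair <- rbind(raw[i, j, ], raw[j, i, ])
      dspread <- max(dspread, max(apply(pair, 2, function(x) max(x) - min(x))))
      d2[i, j, ] <- d2[j, i, ] <- colMeans(pair)
    }
    for (i in seq_len(M))
      d3[i, , ] <- (disp$dgrad_plus[[i]] - 2 * disp$dgrad0 + disp$dgrad_minus[[i]]) / step^2
  } else {
    d2 <- NULL; d3 <- NULL
  }

  ff <- anharmonic_ff(omega, cubic, quartic,
                      level_tag = if (!is.null(disp$level_tag)) disp$level_tag else "finite-difference",
                      step = step)
  attr(ff$cubic, "fd_spread") <- spread_max
  attr(ff$quartic, "fd_spread") <- qspread
  d1 <- if (!is.null(disp$dgrad0)) disp$dgrad0 else matrix(0, M, 3)
  dip <- dipole_surface(mu0 = if (!is.null(disp$mu0)) disp$mu0 else c(0, 0, 0),
                        d1 = d1, d2 = d2, d3 = d3)
  attr(dip$d2, "fd_spread") <- dspread
  list(ff = ff, dip = dip)
}

#' Convert mass-weighted derivatives to dimensionless normal coordinates
#'
#' Applies the per-index scaling \eqn{q_i = Q_i\sqrt{2\pi c\tilde\omega_i/\hbar}}
#' to a derivative tensor over mode indices: an order-n derivative in
#' mass-weighted units (energy in cm^-1, coordinates in \eqn{\sqrt{u}\,\AA})
#' is divided by the product of the scale factors \code{\link{q_scale}} of
#' its indices.  For a harmonic mode this maps the mass-weighted force
#' constant onto its wavenumber: the reduced second derivative along a mode
#' of 1600 cm^-1 is 1600 cm^-1.
#'
#' @param derivs numeric array whose dimensions are all M (one per
#'   differentiation index); a vector is treated as order 1.
#' @param basis a \code{\link{normal_mode_basis}} providing the wavenumbers.
#' @param unit unit tag of the input: \code{"mass-weighted"}
#'   (cm^-1 / (sqrt(u) Angstrom)^n) or \code{"reduced"} (no-op).
#' @return array of the same shape in reduced units (cm^-1).
#' @export
to_reduced_units <- function(derivs, basis, unit = c("mass-weighted", "reduced")) {
  if (!unit[1] %in% c("mass-weighted", "reduced"))
    stop("unknown unit tag: ", unit[1])
  unit <- match.arg(unit)
  if (unit == "reduced") return(derivs)
  omega <- basis$omega
  M <- length(omega)
  s <- q_scale(omega)
  d <- if (is.null(dim(derivs))) length(derivs) else dim(derivs)
  if (!all(d == M)) stop("derivative tensor dimensions must all equal the number of modes")
  n_ord <- if (is.null(dim(derivs))) 1L else length(dim(derivs))
  scale <- Reduce(function(a, b) outer(a, b), rep(list(1 / s), n_ord))
  derivs * scale
}

#' Convert a mass-weighted displacement step to dimensionless coordinates
#'
#' A step of \code{step_mw} \eqn{\sqrt{u}\,\AA} along the mass-weighted
#' coordinate of a mode corresponds to a dimensionless displacement
#' \code{step_mw * q_scale(omega)} that differs per mode.
#'
#' @param step_mw step in sqrt(u) Angstrom (e.g. 0.01).
#' @param omega mode wavenumber(s), cm^-1.
#' @return dimensionless step(s).
#' @export
reduced_step <- function(step_mw, omega) step_mw * q_scale(omega)
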