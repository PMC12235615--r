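#' Integrated IR intensity of a transition
#'
#' Converts a transition energy and dipole transition moment into an
#' integrated molar absorption intensity in km/mol,
#' \eqn{I = C\,\tilde\nu\,|\mu_{fi}|^2}, with the prefactor \eqn{C =
#' 2\pi^2 N_A/(3 h c \varepsilon_0)} assembled from CODATA constants
#' (\eqn{C \approx 2.50664} km/mol per cm^-1 debye^2).  In the
#' double-harmonic limit this reproduces the standard convention (42.2561
#' km/mol for \eqn{\partial\mu/\partial Q = 1} D \eqn{\AA^{-1} u^{-1/2}}).
#' Absorption from the vibrational ground state at 0 K only.
#'
#' @param nu transition energy, cm^-1 (> 0).
#' @param mu transition moment: 3-vector in debye, or an n x 3 matrix
#'   matching a vector \code{nu}.
#' @return intensity (vector), km/mol.
#' @examples
#' ir_intensity(1000, c(1 / sqrt(2), 0, 0))   # harmonic fundamental, d1 = 1 D
#' @export
ir_intensity <- function(nu, mu) {
  if (is.null(dim(mu))) mu <- matrix(mu, ncol = 3)
  stopifnot(all(nu > 0), nrow(mu) == length(nu))
  ir_prefactor() * nu * rowSums(mu^2)
}

#' Lorentzian convolution of a stick spectrum
#'
#' Each stick of intensity I at \eqn{\nu_0} contributes
#' \eqn{I\,(\gamma/\pi)/((\nu-\nu_0)^2+\gamma^2)} with \eqn{\gamma} the
#' half-width at half-maximum, so the convolved curve is an intensity
#' density (km mol^-1 cm) whose integral over a band recovers the km/mol
#' stick intensity.
#'
#' @param energy stick positions, cm^-1.
#' @param intensity stick intensities, km/mol.
#' @param hwhm Lorentzian half-width at half-maximum, cm^-1 (default 1).
#' @param step uniform grid step, cm^-1 (default 0.1).
#' @param range length-2 grid range; defaults to the stick range padded by
#'   50 half-widths on each side.
#' @param normalize divide by the curve maximum (for figure-style
#'   comparison of line shapes).
#' @return data frame of class \code{convolved_spectrum} with columns
#'   \code{nu} and \code{absorption}.
#' @export
convolve_spectrum <- function(energy, intensity, hwhm = 1, step = 0.1,
                              range = NULL, normalize = FALSE) {
  stopifnot(hwhm > 0, step > 0, length(energy) == length(intensity))
  if (!length(energy)) {
    warning("empty stick list; returning an empty spectrum")
    out <- data.frame(nu = numeric(0), absorption = numeric(0))
    class(out) <- c("convolved_spectrum", "data.frame")
    return(out)
  }
  if (is.null(range)) range <- c(min(energy) - 50 * hwhm, max(energy) + 50 * hwhm)
  grid <- seq(range[1], range[2], by = step)
  vals <- numeric(length(grid))
  for (s in seq_along(energy)) {
    vals <- vals + intensity[s] * (hwhm / pi) / ((grid - energy[s])^2 + hwhm^2)
  }
  if (normalize && max(vals) > 0) vals <- vals / max(vals)
  out <- data.frame(nu = grid, absorption = vals)
  attr(out, "hwhm") <- hwhm
  attr(out, "step") <- step
  class(out) <- c("convolved_spectrum", "data.frame")
  out
}

#' Per-region band report
#'
#' Splits the computed states over spectral regions (half-open intervals,
#' lower bound inclusive; defaults: below 1000, 1000-1800, 1800-2900
#' (dominated by nonfundamental bands), 2900-3600 (CH/NH stretches), above
#' 3600 cm^-1) and tabulates energy, intensity per flavor and composition.
#'
#' @param fit a \code{\link{gvpt2}} object.
#' @param boundaries increasing numeric vector of region edges, cm^-1.
#' @return named list of data frames, one per region (empty regions keep
#'   their header).
#' @export
band_report <- function(fit, boundaries = c(1000, 1800, 2900, 3600)) {
  stopifnot(inherits(fit, "gvpt2"), !is.unsorted(boundaries, strictly = TRUE))
  tab <- stick_table(fit)
  edges <- c(-Inf, boundaries, Inf)
  labels <- c(sprintf("below %g", boundaries[1]),
              if (length(boundaries) > 1)
                sprintf("%g-%g", boundaries[-length(boundaries)], boundaries[-1]),
              sprintf("above %g", boundaries[length(boundaries)]))
  out <- lapply(seq_along(labels), function(r) {
    tab[tab$energy >= edges[r] & tab$energy < edges[r + 1], , drop = FALSE]
  })
  names(out) <- labels
  out
}

#' Stick table of a GVPT2 calculation
#'
#' @param fit a \code{\link{gvpt2}} object.
#' @return data frame with columns index, energy (cm^-1), I_full, I_mech,
#'   I_elec, I_harm (km/mol) and composition, sorted by energy.
#' @export
stick_table <- function(fit) {
  stopifnot(inherits(fit, "gvpt2"))
  st <- fit$states
  data.frame(index = st$index, energy = st$energy,
             I_full = fit$intensity$full, I_mech = fit$intensity$mech,
             I_elec = fit$intensity$elec, I_harm = fit$intensity$harm,
             composition = st$composition, stringsAsFactors = FALSE)
}

#' @export
print.convolved_spectrum <- function(x, ...) {
  cat("<convolved_spectrum> ", nrow(x), " points",
      if (nrow(x)) sprintf(", %g..%g cm^-1, hwhm %g", min(x$nu), max(x$nu),
                           attr(x, "hwhm")), "\n", sep = "")
  invisible(x)
}

#' @export
plot.convolved_spectrum <- function(x, xlab = expression(tilde(nu) ~ (cm^-1)),
                                    ylab = "absorption", type = "l", ...) {
  graphics::plot(x$nu, x$absorption, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write a convolved spectrum as two-column delimited text
#'
#' @param x a \code{convolved_spectrum}.
#' @param path output file.
#' @param sep column separator.
#' @export
write_spectrum <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
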