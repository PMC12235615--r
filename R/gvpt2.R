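#' Anharmonic vibrational states and IR intensities by GVPT2
#'
#' The main engine.  Starting from a quartic force field and a dipole
#' surface in dimensionless normal coordinates it
#' \enumerate{
#'   \item enumerates the vibrational states (up to \code{max_quanta} total
#'     quanta within an harmonic-energy window),
#'   \item detects Fermi and Darling-Dennison resonances with the threshold
#'     criteria of \code{\link{resonance_thresholds}},
#'   \item computes deperturbed VPT2 energies (singular Fermi fractions of
#'     the \eqn{\chi} matrix removed) and deperturbed transition moments
#'     (IDVPT2: singular terms of every flagged resonance removed from the
#'     perturbative sums),
#'   \item groups resonance-connected states into polyads, builds the
#'     variational matrices (deperturbed energies on the diagonal, couplings
#'     of accepted edges off-diagonal) and diagonalizes them, and
#'   \item projects the deperturbed moments onto the eigenstates and
#'     converts them into IR intensities (km/mol).
#' }
#' With \code{method = "idvpt2"} the variational step is skipped (states
#' keep their deperturbed energies and moments); with \code{method = "vpt2"}
#' no resonance treatment is applied at all (plain VPT2, which diverges near
#' exact resonances).
#'
#' @param ff an \code{\link{anharmonic_ff}} (for hybrid models, the merged
#'   field whose \code{omega} are the high-level wavenumbers).
#' @param dip a \code{\link{dipole_surface}}.
#' @param max_quanta maximum total quanta of the state space (2 default, 3
#'   adds 3-quanta energies; direct 3-quanta moments are not computed, such
#'   states gain intensity only through polyad mixing).
#' @param method \code{"gvpt2"} (default), \code{"idvpt2"} or \code{"vpt2"}.
#' @param thresholds a \code{\link{resonance_thresholds}}.
#' @param e_window harmonic-energy window for state enumeration, cm^-1.
#' @param moment_removal \code{"all"} removes singular terms of every
#'   resonance kind from the transition moments (IDVPT2, default);
#'   \code{"fermi"} is the legacy mode removing only Fermi terms.
#' @return an object of class \code{gvpt2}: list with \code{states} (data
#'   frame: index, label, quanta, harmonic, deperturbed and final energies,
#'   polyad id, composition), \code{moments} and \code{intensity} (per
#'   flavor), \code{edges}, \code{polyads}, \code{chi}, \code{omega},
#'   \code{config}.
#' @examples
#' toy <- coupled_fermi_ff(delta = 5, f122 = 40)
#' fit <- gvpt2(toy$ff, toy$dip)
#' print(fit)
#' @export
gvpt2 <- function(ff, dip, max_quanta = 2,
                  method = c("gvpt2", "idvpt2", "vpt2"),
                  thresholds = resonance_thresholds(),
                  e_window = c(0, Inf),
                  moment_removal = c("all", "fermi")) {
  method <- match.arg(method)
  moment_removal <- match.arg(moment_removal)
  stopifnot(inherits(ff, "anharmonic_ff"), inherits(dip, "dipole_surface"))
  omega <- ff$omega
  M <- length(omega)
  flavors <- c("full", "mech", "elec", "harm")

  states <- enumerate_states(omega, max_quanta, e_window)
  n <- nrow(states)
  if (n == 0) stop("no states in the requested energy window")

  if (method == "vpt2") {
    edges <- empty_edges()
  } else {
    edges <- detect_resonances(ff, thresholds, omega, max_quanta)
  }
  triples <- fermi_triples(edges)
  keys_all <- registry_keys(edges, M)
  keys_moment <- if (moment_removal == "all") keys_all else
    registry_keys(edges[edges$kind == "fermi", , drop = FALSE], M)

  chi <- vpt2_chi(ff, removed = triples)
  e_dvpt2 <- apply(states, 1, vpt2_transition_energy, omega = omega, chi = chi)

  ops <- ff_operators(ff)
  moments <- lapply(flavors, function(f) matrix(0, n, 3))
  names(moments) <- flavors
  tot <- rowSums(states)
  for (r in seq_len(n)) {
    if (tot[r] > 2) next                     # no direct 3-quanta moments
    mm <- vpt2_moments(states[r, ], ff, dip, keys_moment, ops = ops)
    for (f in flavors) moments[[f]][r, ] <- mm[[f]]
  }

  energy <- e_dvpt2
  final_moments <- moments
  polyad_id <- rep(NA_integer_, n)
  composition <- sprintf("1.000 |%s>", rownames(states))
  polyads <- list()
  if (method == "gvpt2") {
    comps <- build_polyads(states, edges)
    for (p in seq_along(comps)) {
      members <- comps[[p]]
      vc <- variational_correct(members, states, attr(comps[[p]], "edges"),
                                e_dvpt2, moments)
      energy[members] <- vc$energies
      for (f in flavors) final_moments[[f]][members, ] <- vc$moments[[f]]
      polyad_id[members] <- p
      for (s in seq_along(members)) {
        composition[members[s]] <-
          describe_polyad(vc$vectors[, s], rownames(states)[members])
      }
      polyads[[p]] <- vc
    }
  }

  ord <- order(energy)
  states_df <- data.frame(
    index = seq_len(n),
    label = rownames(states)[ord],
    harmonic = attr(states, "energy")[ord],
    deperturbed = e_dvpt2[ord],
    energy = energy[ord],
    polyad = polyad_id[ord],
    composition = composition[ord],
    stringsAsFactors = FALSE)
  moments_ord <- lapply(final_moments, function(m) m[ord, , drop = FALSE])
  dvpt2_moments_ord <- lapply(moments, function(m) m[ord, , drop = FALSE])
  intensity <- lapply(moments_ord, function(m) ir_intensity(states_df$energy, m))

  structure(list(
    states = states_df,
    quanta = states[ord, , drop = FALSE],
    moments = moments_ord,
    dvpt2_moments = dvpt2_moments_ord,
    intensity = intensity,
    edges = edges,
    polyads = polyads,
    chi = chi,
    omega = omega,
    method = method,
    config = list(max_quanta = max_quanta, thresholds = thresholds,
                  e_window = e_window, moment_removal = moment_removal,
                  intensity_prefactor = signif(ir_prefactor(), 6))),
    class = "gvpt2")
}

#' @export
print.gvpt2 <- function(x, ...) {
  cat("GVPT2 anharmonic calculation (", x$method, ")\n", sep = "")
  cat("  modes:", length(x$omega), "  states:", nrow(x$states),
      "  accepted resonances:", sum(x$edges$accepted),
      "  polyads:", length(x$polyads), "\n")
  tab <- utils::head(stick_table(x)[order(-stick_table(x)$I_full), ], 5)
  cat("  strongest bands (cm^-1, km/mol):\n")
  for (r in seq_len(nrow(tab)))
    cat(sprintf("    %9.2f  %8.3f  %s\n", tab$energy[r], tab$I_full[r],
                tab$composition[r]))
  invisible(x)
}

#' @export
summary.gvpt2 <- function(object, ...) {
  acc <- object$edges[object$edges$accepted, , drop = FALSE]
  structure(list(fit = object, accepted = acc,
                 n_by_kind = table(acc$kind)), class = "summary.gvpt2")
}

#' @export
print.summary.gvpt2 <- function(x, ...) {
  print(x$fit)
  if (nrow(x$accepted)) {
    cat("  accepted resonance edges:\n")
    for (r in seq_len(nrow(x$accepted)))
      cat(sprintf("    %-6s |%s> ~ |%s>  delta = %8.2f  W = %8.3f cm^-1\n",
                  x$accepted$kind[r], x$accepted$bra[r], x$accepted$ket[r],
                  x$accepted$delta[r], x$accepted$W[r]))
  } else cat("  no accepted resonances\n")
  invisible(x)
}

#' Anharmonicity constants of a fitted GVPT2 object
#'
#' @param object a \code{\link{gvpt2}} object.
#' @param ... unused.
#' @return the (deperturbed) chi matrix, cm^-1.
#' @export
coef.gvpt2 <- function(object, ...) object$chi

#' Plot the convolved IR spectrum of a GVPT2 calculation
#'
#' @param x a \code{\link{gvpt2}} object.
#' @param flavor intensity flavor to plot.
#' @param hwhm,step Lorentzian half-width and grid step, cm^-1.
#' @param ... passed to \code{\link{plot.convolved_spectrum}}.
#' @export
plot.gvpt2 <- function(x, flavor = "full", hwhm = 1, step = 0.1, ...) {
  sp <- convolve_spectrum(x$states$energy, x$intensity[[flavor]],
                          hwhm = hwhm, step = step)
  plot(sp, ...)
  invisible(sp)
}
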