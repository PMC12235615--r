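#' Vibrational basis states labelled by harmonic quanta
#'
#' A vibrational state is represented by an integer vector of quanta, one
#' entry per normal mode.  Mode numbering follows the spectroscopic order
#' (grouped by irreducible representation, decreasing harmonic wavenumber
#' within a group; without symmetry labels all modes form one block sorted by
#' decreasing wavenumber).
#'
#' @param quanta integer vector of length M (number of modes), all >= 0.
#' @return an integer vector of class \code{vib_state}.
#' @examples
#' s <- vib_state(c(0, 1, 1))
#' state_label(s)   # "2^1 3^1"
#' @export
vib_state <- function(quanta) {
  q <- as.integer(quanta)
  if (any(q < 0)) stop("quanta must be non-negative")
  structure(q, class = "vib_state")
}

#' Deterministic label of a vibrational state
#'
#' Formats a state as a list of excited modes with their quanta in
#' superscript notation, e.g. \code{"4^1 6^1"} for the binary combination of
#' modes 4 and 6.  The ground state is labelled \code{"0"}.
#'
#' @param quanta integer vector of quanta (or a \code{vib_state}).
#' @return character scalar.
#' @export
state_label <- function(quanta) {
  idx <- which(quanta > 0)
  if (length(idx) == 0) return("0")
  paste(sprintf("%d^%d", idx, quanta[idx]), collapse = " ")
}

#' @export
print.vib_state <- function(x, ...) {
  cat("<vib_state> |", state_label(x), ">\n", sep = "")
  invisible(x)
}

state_key <- function(quanta) paste(quanta, collapse = ",")

#' Enumerate low-lying vibrational states
#'
#' All states with total quanta between 1 and \code{max_quanta} whose harmonic
#' energy lies in \code{e_window} (half-open, lower-inclusive), in a
#' deterministic order: by harmonic energy, ties broken lexicographically by
#' the quanta vector.
#'
#' @param omega harmonic wavenumbers, cm^-1 (length M).
#' @param max_quanta maximum total quanta (1, 2 or 3).
#' @param e_window numeric length-2, harmonic-energy window in cm^-1.
#' @return integer matrix, one row per state, M columns; row names are state
#'   labels, attribute \code{"energy"} holds the harmonic energies.
#' @examples
#' enumerate_states(c(1600, 800), max_quanta = 2)
#' @export
enumerate_states <- function(omega, max_quanta = 2, e_window = c(0, Inf)) {
  stopifnot(max_quanta %in% 1:3, length(e_window) == 2)
  M <- length(omega)
  rows <- list()
  # compositions of n quanta over M modes, n = 1..max_quanta
  add <- function(q) rows[[length(rows) + 1]] <<- q
  for (i in seq_len(M)) add(as.integer(replace(integer(M), i, 1L)))
  if (max_quanta >= 2) {
    for (i in seq_len(M)) for (j in i:M) {
      q <- integer(M); q[i] <- q[i] + 1L; q[j] <- q[j] + 1L
      add(q)
    }
  }
  if (max_quanta >= 3) {
    for (i in seq_len(M)) for (j in i:M) for (k in j:M) {
      q <- integer(M); q[i] <- q[i] + 1L; q[j] <- q[j] + 1L; q[k] <- q[k] + 1L
      add(q)
    }
  }
  S <- do.call(rbind, rows)
  e <- as.numeric(S %*% omega)
  keep <- e >= e_window[1] & e < e_window[2]
  S <- S[keep, , drop = FALSE]; e <- e[keep]
  if (nrow(S)) {
    ord <- do.call(order, c(list(e), lapply(seq_len(M), function(m) S[, m])))
    S <- S[ord, , drop = FALSE]; e <- e[ord]
    rownames(S) <- apply(S, 1, state_label)
  }
  attr(S, "energy") <- e
  S
}
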