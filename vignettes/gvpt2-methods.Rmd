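---
title: "Anharmonic IR spectra by generalized second-order vibrational perturbation theory"
author: "gvpt2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anharmonic IR spectra by generalized second-order vibrational perturbation theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvpt2)
```

## The model

The package starts from a quartic expansion of the potential energy in
dimensionless normal coordinates $q$,

$$V(q) = \frac{1}{2}\sum_i \omega_i q_i^2
       + \frac{1}{6}\sum_{ijk} f_{ijk}\, q_i q_j q_k
       + \frac{1}{24}\sum_{ijkl} f_{ijkl}\, q_i q_j q_k q_l ,$$

with $\omega_i$ the harmonic wavenumbers and all force constants in
cm$^{-1}$ (the quartic set is semidiagonal: every stored entry has at least
two equal indices, the standard output of finite differentiation of
analytical Hessians).  The dipole surface is expanded to the same order:
first, second and semidiagonal third derivatives, in debye per unit $q$.

Second-order perturbation theory (VPT2) on this Hamiltonian gives
anharmonicity constants $\chi_{ij}$ and state energies
$E(n) = \sum_i \omega_i (n_i + \tfrac12) + \sum_{i \le j} \chi_{ij}
(n_i+\tfrac12)(n_j+\tfrac12)$.  The implementation writes every
cubic-squared contribution to $\chi$ in partial-fraction form, e.g.

$$\chi_{ij} \supset -\frac{f_{ijk}^2}{8}\left[
  \frac{1}{\omega_i+\omega_j+\omega_k} +
  \frac{1}{\omega_j+\omega_k-\omega_i} +
  \frac{1}{\omega_i+\omega_k-\omega_j} -
  \frac{1}{\omega_i+\omega_j-\omega_k}\right],$$

so that each potentially resonant fraction is tied to exactly one Fermi
triple $(i,(j,k))$ and can be removed individually.  This partial-fraction
form was derived from the explicit sum-over-states second-order energy and
is verified in the tests both against the VCI oracle and against a
detuning-limit study of the removed fraction.

## Transition moments

Rather than transcribing the lengthy closed-form VPT2 transition-moment
expressions, the package evaluates them by explicit Rayleigh–Schrödinger
perturbation theory in the harmonic-oscillator product basis, using exact
ladder-operator algebra ($\langle n+1|q|n\rangle = \sqrt{(n+1)/2}$).  With
the usual ordering — cubic potential first order, quartic second order,
dipole derivatives $d_1/d_2/d_3$ of orders 0/1/2 — the ground-to-state
moment is assembled term by term:

* **fundamentals**: all contributions through second order, i.e. the
  harmonic moment, mechanical terms ($d_1$ with first- and second-order
  wave functions, including the normalization correction), electrical terms
  ($d_3$ with harmonic wave functions) and the mixed
  electrical–mechanical terms ($d_2$ with first-order wave functions);
* **overtones and binary combinations**: all contributions through first
  order ($d_2$ with harmonic wave functions plus $d_1$ with first-order
  wave functions), so the full moment splits exactly into a mechanical and
  an electrical part with no mixed term.

This is algebraically identical to the closed forms at the same order, and
it makes deperturbation transparent: every term carries one or two energy
denominators $E_n - E_v$ that are known signed combinations of harmonic
wavenumbers, and a flagged resonance removes precisely the terms carrying
its combination (the intensity-extended deperturbation, IDVPT2, removes
singular terms of every resonance kind; a legacy mode removes only Fermi
terms).  The correctness arbiter is the variational oracle below, not a
transcription: on weakly anharmonic random fields the full fundamental
moments agree with VCI to better than 0.1% and 2-quanta moments to within
5%.

The four intensity *flavors* exposed throughout (`full`, `mech`, `elec`,
`harm`) select subsets of these terms; by construction `full = mech + elec`
holds exactly for 2-quanta states, and the mixed term for fundamentals
vanishes whenever either the dipole expansion is linear or the cubic force
constants vanish.

## Resonance detection, deperturbation, variational correction

Near-degeneracies make individual perturbative terms singular.  The engine
follows the three-step protocol: identify, deperturb, correct variationally.

Fermi candidates $\omega_i \approx \omega_j + \omega_k$ are accepted when
all three criteria pass (defaults in `resonance_thresholds()`):

* detuning window $|\Delta| \le 200$ cm$^{-1}$,
* variational depth $f_{ijk}^4 / (64 (1+\delta_{jk})^2 |\Delta|^3) \ge 1$ cm$^{-1}$,
* perturbation ratio $|f_{ijk}/(8(1+\delta_{jk})\Delta)| \ge 0.1$.

The Kronecker factor distinguishes overtone from combination partners; a
printed variant attaching it to the $(i,j)$ pair exists in the literature,
and this implementation consistently uses $\delta_{jk}$ in both criteria (a
configuration note, not a resolved ambiguity).  An exactly degenerate
candidate ($\Delta = 0$) with a nonzero constant is auto-accepted with
infinite diagnostics: any finite coupling at zero detuning is a resonance
by construction.

Darling–Dennison candidates (1-1 between fundamentals, 2-2 between
2-quanta states, 1-3 between a fundamental and a 3-quanta state) use a
100 cm$^{-1}$ window, a minimum effective coupling $|W| \ge 10$ cm$^{-1}$
and, for 1-1 and 1-3, a minimum second-order mixing coefficient (1 and 0.3
respectively).  The couplings are second-order Van Vleck
(contact-transformation) matrix elements

$$W_{ab} = \langle a|V_4|b\rangle + \frac{1}{2}\sum_{u \ne a,b}
  \langle a|V_3|u\rangle\langle u|V_3|b\rangle
  \left[\frac{1}{E_a-E_u} + \frac{1}{E_b-E_u}\right],$$

evaluated with the same ladder algebra; for Fermi pairs the first-order
element $\langle a|V_3|b\rangle$ applies ($f_{ijk}/2\sqrt2$ against a
combination, $f_{ijj}/4$ against an overtone).  Intermediates already
connected to either partner by an accepted Fermi edge, or within
0.1 cm$^{-1}$ of degeneracy, are excluded from the transformation — they
belong inside the variational space.  The closed forms of these couplings
are not tabulated here; the implementation is gated by the VCI oracle
(e.g. the two-state splitting $\sqrt{\Delta^2 + 4W^2}$ of an engineered 1-1
pair is reproduced to about 2%).  The mixing coefficient is taken as
$|W/\Delta|$ on harmonic detunings, the leading second-order expression,
with auto-acceptance at $\Delta = 0$.

Accepted edges define a graph over the enumerated states; its connected
components are the polyads.  Each polyad matrix carries deperturbed
energies on the diagonal and the couplings $W$ of accepted edges
off-diagonal — entries between members whose pair was not itself flagged
stay exactly zero, with no second-pass fill-in.  Diagonalization yields the
final (GVPT2) energies; transition moments are projected onto the
eigenvectors, $\mu_s = \sum_v c_{vs}\,\mu_v^{\mathrm{IDVPT2}}$, per flavor.
Both the eigenvalue trace and the squared-moment norm are conserved per
polyad to $10^{-10}$ relative (asserted over seeded random fields).
Eigenvector phases are fixed by making the largest-magnitude coefficient
positive, ties broken by the lowest member index, so composition strings
such as `0.953 |7^1>` are reproducible; coefficients below 0.2 are kept in
the data but omitted from the printed string (matching the smallest
coefficients one typically reports, about 0.22).

States are labelled by their harmonic quanta in spectroscopic order
(grouped by irreducible representation, decreasing wavenumber within a
group; without irrep labels, one block by decreasing wavenumber), and final
GVPT2 states are indexed 1-based by increasing corrected energy.

## Hybrid force fields

Harmonic quantities from a high-level electronic-structure calculation can
be combined with anharmonic derivatives from a cheaper one, provided the
two sets of normal coordinates are essentially identical.  Similarity is
measured by the Duschinsky overlap $J = L_\mathrm{high}^T L_\mathrm{low}$;
modes are matched greedily by descending $J_{ik}^2$ (ties by lower index)
and accepted at $J_{ik}^2 \ge 0.9$.  Greedy assignment is not prescribed
anywhere; it is deterministic and unambiguous at this threshold, which is
why it was chosen.  Any unmatched mode is a hard error — the Taylor-split
argument underlying the hybrid is invalid for non-identical coordinates, so
a silent fallback would be worse than a failure.

Three schemes are provided: `freq` (high-level wavenumbers only, no tensor
remapping — the literature-data case; a warning flags ambiguous
energy-order pairing), `pes` (high-level wavenumbers and coordinates;
low-level tensors re-indexed and re-signed through the mapping, odd-order
tensors picking up the product of their index signs) and `pes+ps` (`pes`
plus high-level dipole first derivatives).  In all three the high-level
wavenumbers feed the VPT2 formulas and the resonance analysis.  The merge
is exact: re-merging a permuted, sign-flipped copy of a field reproduces
the original tensors bitwise, and `pes` vs `pes+ps` differ in intensities
only, never in energies.

## Intensities and band shapes

Integrated intensities are
$I = C\,\tilde\nu\,|\langle\psi_0|\mu|\psi_f\rangle|^2$ with
$C = 2\pi^2 N_A / (3 h c \varepsilon_0) = 2.50664$ km/mol per
cm$^{-1}$ debye$^2$, assembled from CODATA values (the double-harmonic
limit then gives the conventional 42.2561 km/mol for
$\partial\mu/\partial Q = 1$ D Å$^{-1}$ u$^{-1/2}$).  Only absorption from
the vibrational ground state is computed (0 K; no hot bands).

Band shapes are Lorentzian, half-width at half-maximum 1 cm$^{-1}$ on a
0.1 cm$^{-1}$ grid by default.  The convolved curve is an intensity
density (km mol$^{-1}$ cm) whose band integral recovers the stick
intensity; a normalized-to-maximum output is available for figure-style
line-shape comparison.  Spectral-region reports use half-open,
lower-inclusive intervals with default boundaries 1000, 1800, 2900 and
3600 cm$^{-1}$.

## Synthetic model systems and the variational oracle

Three generators produce complete basis/force-field/dipole triples:

* `morse_ff()` — the quartic truncation of a Morse oscillator
  ($f_3 = -6D\alpha^3$, $f_4 = 14D\alpha^4$, $\alpha = \sqrt{\omega/2D}$).
  VPT2 on this truncation reproduces the exact Morse anharmonicity
  $\omega x_e = \omega^2/4D$, which makes the full Morse ladder an analytic
  target at $10^{-10}$ relative accuracy.
* `coupled_fermi_ff()` — the textbook bright-fundamental/dark-overtone
  Fermi pair with a single cubic channel $f_{122}$, placeable anywhere in
  the (detuning, coupling) plane.  The dipole defaults (bright
  $d_1 = 0.3$ D, dark mode 0.05 D, no higher derivatives) are ordinary
  mid-IR magnitudes chosen once for the study conditions.
* `random_ff()` — seeded random fields, $\omega \sim U[400, 1800]$
  cm$^{-1}$ with a minimum pairwise gap of 150 cm$^{-1}$ so that
  perturbation-validity tests are not confounded by accidental resonances;
  an option forces $\omega_1 \approx \omega_2 + \omega_3$ within
  20 cm$^{-1}$ when resonant physics is wanted.  Default magnitudes
  ($|f_3| \le 0.03\,\min\omega$, $|f_4|$ ten times smaller) keep the
  fields inside the perturbative regime.

`vci_solve()` diagonalizes the *same truncated quartic Hamiltonian* the
perturbative engine consumes, in a product basis capped by total quanta,
with transition moments from the same dipole expansion.  Oracle-vs-VPT2
discrepancies therefore measure the perturbative error only; comparisons
against the untruncated Morse ladder are separate, labelled checks.  The
oracle is limited to 4 modes and reports a convergence estimate (level
shifts upon enlarging the basis by 4 quanta, flagged above 0.1 cm$^{-1}$).

What the toys do *not* emulate: rotational/Coriolis structure, symmetry
blocks with degenerate irreps, dense mid-IR mode manifolds, and
electronic-structure noise in the derivatives.  Passing tests demonstrate
the correctness of the vibrational treatment on clean quartic fields, not
the accuracy of any particular electronic-structure level on real
molecules.

## Numerical choices

* Tensor symmetry: redundant entries are cross-checked; spreads up to
  $10^{-3}$ cm$^{-1}$ are averaged with a warning (finite-difference noise),
  larger spreads are validation errors naming the indices.
* Exact zero denominators in unflagged terms raise errors instructing to
  flag the resonance; near-singular unflagged denominators are left to the
  detection thresholds — no damping or switching functions, matching the
  remove-then-diagonalize protocol.
* Finite differences: central formulas exact on quartic potentials for any
  step; permutation-equivalent estimates averaged, spreads reported.  The
  differentiation step may be given mass-weighted (e.g. 0.01 $\sqrt{u}$ Å,
  converted per mode via `q_scale()`) or dimensionless.
* Coriolis and rotational contributions to $\chi$ are omitted: the AFF
  format carries no $\zeta$ constants or rotational constants, and all
  oracle fixtures are rotation-free.  For real molecules this costs a few
  cm$^{-1}$ on some constants; an extension would add a $\zeta$ section to
  the format and the corresponding $\chi$ terms.
* $\chi_0$ (the state-independent term) is not computed — every reported
  observable is a transition.
* Problem sizes: tests and the acceptance script run 1–3-mode fields with
  VCI bases of 10–60 total quanta and 20-seed property scans; these sizes
  make every oracle comparison converged and the whole suite fast.

## Known limitations

* 2-quanta transition moments are first order (the order at which the
  mechanical/electrical split is exact).  Near a resonance that the
  thresholds reject — for example a Fermi pair at detuning 50 cm$^{-1}$
  with $W \approx 10$ cm$^{-1}$, mixing $c = W/\Delta \approx 0.2$ — the
  residual error of the perturbative overtone *intensity* grows as $c^2$
  and can reach 10–20% while energies stay within a fraction of a
  cm$^{-1}$; the VCI comparisons in the test suite quantify exactly this.
  Tightening is possible only by widening the detection window, which is a
  protocol change, not a numerical fix.
* Direct 3-quanta moments are not computed; 3-quanta states acquire
  intensity only through polyad mixing.
* Non-Abelian symmetry (degenerate modes), vibrational averaging of
  properties, Raman/VCD observables and temperature effects are out of
  scope.

## A worked Fermi resonance

```{r fermi}
toy <- coupled_fermi_ff(delta = 5, f122 = 40)
fit <- gvpt2(toy$ff, toy$dip)
summary(fit)
fit$states[, c("index", "label", "deperturbed", "energy", "composition")]
```

The accepted edge couples the bright fundamental to the dark overtone
($W = f_{122}/4 = 10$ cm$^{-1}$); diagonalizing the 2×2 polyad pushes the
pair apart and redistributes the intensity, which the oracle confirms:

```{r oracle}
v <- vci_solve(toy$ff, toy$dip, basis_max_quanta = 24)
head(cbind(E_vci = v$transition_energy,
           I_vci = ir_intensity(v$transition_energy, v$moments)), 4)
```
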