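# gvpt2 — anharmonic IR spectra from quartic force fields

`gvpt2` turns a quartic force field and a dipole-derivative surface into an
anharmonic infrared spectrum using generalized second-order vibrational
perturbation theory (GVPT2).  It is aimed at computational spectroscopists
who already have cubic/semidiagonal-quartic force constants and dipole
derivatives (from finite differentiation of analytical Hessians at any
electronic-structure level) and need reliable anharmonic band positions
*and intensities*, including the resonance-perturbed regions where plain
VPT2 diverges.

## What it computes

Starting from the expansion in dimensionless normal coordinates
$V = \tfrac12\sum_i \omega_i q_i^2 + \tfrac16\sum f_{ijk} q_iq_jq_k +
\tfrac1{24}\sum f_{ijkl} q_iq_jq_kq_l$ (cm⁻¹) the engine

- computes the VPT2 anharmonicity matrix χ with every resonant denominator
  written as an individually removable partial fraction, and state energies
  $E(n)=\sum_i\omega_i(n_i+\tfrac12)+\sum_{i\le j}\chi_{ij}(n_i+\tfrac12)(n_j+\tfrac12)$;
- detects **Fermi** resonances ($\omega_i\approx\omega_j+\omega_k$; window
  200 cm⁻¹, depth $f^4/(64(1+\delta_{jk})^2|\Delta|^3)\ge 1$ cm⁻¹, ratio
  $|f/(8(1+\delta_{jk})\Delta)|\ge 0.1$) and **Darling–Dennison**
  resonances (1-1, 2-2, 1-3; window 100 cm⁻¹, coupling $|W|\ge 10$ cm⁻¹,
  mixing thresholds 1 and 0.3) with contact-transformation couplings;
- removes the singular terms of flagged resonances from energies and
  transition moments (DVPT2 / intensity-extended IDVPT2), groups
  resonance-connected states into polyads, diagonalizes the variational
  matrices and projects the transition moments onto the eigenstates;
- splits intensities into mechanical (wave-function) and electrical
  (dipole-expansion) anharmonic contributions, converts them to km/mol
  ($I = 2.50664\,\tilde\nu\,|\mu|^2$), and synthesizes Lorentzian band
  shapes (HWHM 1 cm⁻¹, grid 0.1 cm⁻¹ by default);
- merges high-level harmonic and low-level anharmonic surfaces into the
  hybrid schemes **Freq**, **PES** and **PES+PS** after Duschinsky mode
  matching ($J_{ik}^2 \ge 0.9$);
- validates everything against a built-in variational configuration
  interaction (VCI) oracle that diagonalizes the same truncated
  Hamiltonian exactly on up to 4 modes.

Force fields travel in a plain-text, versioned **AFF** format
(`read_aff()` / `write_aff()`, bit-identical round trips), can be
assembled from displaced Hessians by central finite differences
(`aff_from_displacements()`), and converted from mass-weighted to
dimensionless units (`to_reduced_units()`, `q_scale()`).

## Worked example: a Fermi doublet

```r
library(gvpt2)
toy <- coupled_fermi_ff(delta = 5, f122 = 40)   # omega1 = 1600, omega2 = 797.5
fit <- gvpt2(toy$ff, toy$dip)
summary(fit)
```

```
GVPT2 anharmonic calculation (gvpt2)
  modes: 2   states: 5   accepted resonances: 1   polyads: 1 
  strongest bands (cm^-1, km/mol):
      1607.45   115.674  0.801 |1^1> + 0.599 |2^2>
      1586.61    64.805  0.801 |2^2> - 0.599 |1^1>
       797.19     2.499  1.000 |2^1>
      2397.09     0.000  1.000 |1^1 2^1>
      3199.94     0.000  1.000 |1^2>
  accepted resonance edges:
    fermi  |1^1> ~ |2^2>  delta =     5.00  W =   10.000 cm^-1
```

The bright fundamental at a harmonic 1600 cm⁻¹ sits 5 cm⁻¹ above the dark
overtone of mode 2 and couples to it through $W = f_{122}/4 = 10$ cm⁻¹.
GVPT2 deperturbs the singular terms, then diagonalizes the 2×2 polyad: the
doublet splits to 1586.6/1607.5 cm⁻¹ and the overtone borrows more than a
third of the intensity (64.8 vs 115.7 km/mol) — the composition strings
give the eigenvector weights.  The VCI oracle puts the doublet at
1586.60/1607.46 cm⁻¹, within 0.005 cm⁻¹.

```r
coef(fit)               # the (deperturbed) chi matrix, cm^-1
plot(fit)               # Lorentzian-convolved spectrum
band_report(fit)        # per-region tables, all intensity flavors
```

A command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/vibspec.R toys make --kind fermi --delta 5 -o toy.aff
Rscript inst/cli/vibspec.R run --input toy.aff -o out/
Rscript inst/cli/vibspec.R hybrid --scheme pes+ps --high high.aff --low low.aff -o hybrid.aff
```

`run` writes the resonance-edge report (every evaluated candidate with its
diagnostics), the polyad matrices, stick tables for GVPT2 and IDVPT2,
convolved spectra per intensity flavor and a JSON manifest from which a
rerun reproduces all outputs bit-for-bit.

## Scope

Electronic-structure calculations themselves (geometries, Hessians,
functionals) are out of scope: the package consumes their results.
Coriolis/rotational contributions to χ, degenerate (non-Abelian) modes,
hot bands and Raman/VCD observables are not implemented; the methods
vignette (`vignettes/gvpt2-methods.Rmd`) documents the model, the
numerical choices and the known limitations in detail.
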