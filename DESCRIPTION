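Package: gvpt2
Title: Generalized Second-Order Vibrational Perturbation Theory for
    Anharmonic Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns quartic force fields and dipole-derivative surfaces into
    anharmonic infrared spectra with generalized second-order vibrational
    perturbation theory (GVPT2). Includes automated detection of Fermi and
    Darling-Dennison resonances, deperturbation of resonant terms (DVPT2 and
    its intensity-extended variant IDVPT2), variational correction of polyads,
    hybrid merging of high-level harmonic and low-level anharmonic surfaces
    after Duschinsky mode matching, transition moments split into mechanical
    and electrical anharmonic contributions, Lorentzian band-shape synthesis,
    and a variational configuration-interaction oracle for validation on
    small model systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
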