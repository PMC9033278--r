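Package: statecompare
Title: Comparing Mechanosensitive Channel States from ESEEM, HDX-MS and
    Molecular-Dynamics Structural Metrics
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative comparison of membrane-protein conformational
    states across three independent experimental and computational probes.
    Implements solvent-accessibility quantification from three-pulse ESEEM
    (electron spin echo envelope modulation) deuterium time traces by both a
    damped-harmonic-oscillation fit and a Fourier-spectrum route, differential
    hydrogen-deuterium exchange mass spectrometry analysis with a global
    confidence-interval threshold on summed uptake differences and residue
    level region mapping, and trajectory-level structural metrics (Kabsch
    RMSD, helix tilt, membrane thickness, HOLE-style pore radius profiles,
    pore hydration, lipid contacts, acyl-chain order parameters,
    Shrake-Rupley surface area and pairwise Lennard-Jones/Coulomb energies).
    A synthetic-data module generates every input class with known ground
    truth, and a pipeline orchestrates the three arms into a per-residue
    state report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
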