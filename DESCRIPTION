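Package: pkaqsar
Title: Quantum-Chemical QSAR Estimation of Pyrimidine and Heterocycle Acidities
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates acid dissociation constants (pKa) of pyrimidines and
    related nitrogen heterocycles from continuum-solvation deprotonation
    energies via a linear free-energy relationship. Provides tautomer
    microstate resolution (most-stable and Boltzmann-weighted policies),
    construction of the aqueous deprotonation-energy descriptor for the
    cation-to-neutral (pKa1) and neutral-to-anion (pKa2) steps, closed-form
    univariate least-squares calibration with full regression diagnostics,
    consolidation of multi-source literature pKa records, gas-phase acidity
    validation against tabulated Gibbs energies, agreement analysis against
    an external empirical predictor, and a seeded synthetic-data generator
    for end-to-end pipeline testing and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
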