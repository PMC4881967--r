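Package: saxsmc
Title: SAXS-Restrained Hybrid Monte Carlo Sampling of Peptide Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enriches conformational sampling toward a target structure by
    coupling a pluggable conformational propagator with a Metropolis
    structure-acceptance judgment driven by the discrepancy between
    small-angle X-ray scattering (SAXS) intensity profiles of the current
    decoy and the target. Provides a Debye-formula scattering calculator
    with coarse-grained form factors and an optional hydration shell,
    Guinier radius-of-gyration estimation, a family of profile discrepancy
    scores, decoy clustering with a self-adjusting RMSD cutoff, and a full
    sampling-efficiency analysis framework (actual, hypothetical
    ball-overlap, and random-baseline sampling efficiency), together with
    generators for coarse-grained helix, sheet and coil peptide fixtures so
    the whole workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
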