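Package: FlexiFDR
Title: Mass-Calibrated Target-Decoy False Discovery Rates for
    Peptide-Spectrum Matches
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of shotgun proteomics database search results.
    Implements classical target-decoy false discovery rate estimation for
    separate and concatenated searches (q-values, threshold selection,
    I/L-aware decoy filtering) and the FlexiFDR rescoring method: an
    ordinary least-squares regression of decoy search scores on peptide
    mass, fitted per precursor charge state, whose slope is used to
    transform every score into its y-axis intercept (FlexiScore) so that a
    single flat threshold on the transformed scale corresponds to a
    mass-dependent, charge-specific threshold on the raw scale. Also
    provides entrapment-database evaluation of competing FDR procedures
    (confusion counts on method-unique identifications, net positive gain,
    entrapment false discovery proportion) and a seeded synthetic PSM
    generator with the statistical structure the method assumes, so the
    whole pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
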