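Package: abtriage
Title: Antibody Developability Triage from Paired Variable-Domain Sequences
Version: 0.1.0
Authors@R: person("abtriage", "maintainers", email = "abtriage@example.org",
    role = c("aut", "cre"))
Description: A two-layer triaging pipeline for paired heavy/light antibody
    variable-domain sequences. Sequences are filtered on fast physicochemical
    statistics (CDR-H3 length, additive unfolding free energy, isoelectric
    point, cysteine count), numbered on the Chothia scheme and padded onto
    fixed 132/122-slot grids, encoded with pluggable per-residue encoders, and
    gated by an unsupervised rbf kernel-PCA projection with a rotated-ellipse
    capture region built from a clinical reference cloud ('Layer 1'), followed
    by a supervised approved-versus-discontinued linear classifier with
    F-regression feature selection and calibrated probability thresholds
    ('Layer 2'). Includes seeded synthetic generators so the full pipeline is
    testable without external datasets or language-model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
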