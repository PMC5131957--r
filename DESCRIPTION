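Package: p53triplex
Title: Screening Promoters for Co-Occurring p53 Response Elements and
    Intramolecular Triplex-Forming Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for an in-silico screen of TSS-anchored promoter
    windows for p53 consensus response elements (pairs of degenerate
    RRRCWWGYYY half-sites) co-occurring with potential intramolecular
    T.A.T/C.G.C triplex (H-DNA) forming sequences, scored as
    mirror-repeat folds within homopurine/homopyrimidine tracts.
    Includes saturation-binding (Kd) curve fitting with hyperbolic and
    Hill models, EMSA fraction-bound and competition summaries, and a
    synthetic promoter/binding-curve generator with planted features
    and truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
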