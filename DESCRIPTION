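Package: abmature
Title: Computer-Assisted Antibody Affinity Maturation Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for computer-assisted affinity maturation of therapeutic
    antibodies against a protein antigen. Implements interface and epitope
    analysis of antigen-antibody complex structures in PDB format,
    concordance of computational (mCSM-PPI2, FoldX style) and experimental
    alanine scans, five-criterion triage of candidate point mutations with a
    dual-predictor cross-check, sequence liability motif scanning,
    pairwise combination of beneficial mutations, four-parameter-logistic
    IC50 fitting and candidate ranking against a benchmark antibody, and
    RMSD/RMSF trajectory metrics. Includes synthetic-data generators with
    known ground truth so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
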