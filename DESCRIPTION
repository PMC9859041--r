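Package: tcrpmhc
Title: Docking Geometry, Hybrid Templates and Specificity Scoring for
    TCR:pMHC Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational machinery for template-based modeling of T cell
    receptor (TCR) complexes with peptide-MHC (pMHC). Defines MHC and TCR
    coordinate frames from internal pseudo-symmetry, parameterizes the
    rigid-body docking geometry as a six-degree-of-freedom vector with a
    Mahalanobis Z score against the consensus binding mode, and provides
    weighted-RMSD accuracy metrics (CDR RMSD, peptide RMSD, and a
    sequence-independent docking RMSD). Implements TCRdist-style sequence
    distances with redundancy filtering and density-based repertoire
    subsampling, benchmark-mode template exclusion rules, hybrid template
    assembly from single-chain templates plus representative docking
    geometries, and conversion of predicted-aligned-error (PAE) matrices
    from any structure predictor into corrected binding scores, ranks,
    ROC analyses, decoy sets and alanine scans. A synthetic-data module
    generates idealized complexes, PAE matrices and repertoires so the
    whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
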