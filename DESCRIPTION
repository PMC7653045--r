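Package: hervscreen
Title: T Cell Epitope Discovery from Human Endogenous Retroviruses via
    DNA-Barcoded pMHC Multimer Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for large-scale T cell epitope
    screens of human endogenous retroviruses (HERVs) in myeloid malignancies.
    Builds candidate 9-11mer peptide libraries from HERV transcripts by
    first-ORF translation and MHC class I binding-rank filtering; calls
    antigen-specific CD8+ T cell populations from DNA-barcode read counts of
    sorted pMHC-multimer-binding cells using TMM normalization, a one-sided
    negative-binomial test at fixed dispersion, and Benjamini-Hochberg FDR
    control with a read-fraction filter; aggregates detections into
    individual-level responder matrices, epitope catalogs, and per-HERV
    reactivity scores; fits Bayesian cohort-comparison models (conjugate
    binomial proportions and HLA-corrected logistic regression with
    sum-to-zero constraints, posterior contrasts via MCMC) plus a hierarchical
    clinical-outcome model; performs exact rank tests with ties and HERV
    expression (TPM) fold-change and correlation analyses. A synthetic-data
    module generates every pipeline input with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    rjags
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    coda,
    jsonlite
Config/testthat/edition: 3
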