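Package: cafsig
Title: Stromal Origin of EMT Gene Expression Signatures
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing epithelial-to-mesenchymal transition (EMT)
    gene-expression signals to the tumor stroma and cancer-associated
    fibroblasts (CAFs). Implements bulk signature scoring (within-cohort
    z-scores summarized by per-sample medians) and correlation panels
    against purity, immune and stroma scores; dual-species
    patient-derived-xenograft analysis of per-gene mouse (stromal) read
    fractions with preranked permutation gene-set enrichment and
    Benjamini-Hochberg FDR; sentinel-marker mutual-rank co-expression
    expansion for deriving compact cell-type signatures such as the 3-gene
    collagen CAF signature; single-cell QC filtering, 0-100 per-cell
    signature scores, cell-type fold enrichment and Wilcoxon comparisons;
    Cox proportional-hazards association of signature scores with overall
    survival reported as IQR-scaled hazard ratios; and seeded synthetic-data
    generators that emulate each input modality with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
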