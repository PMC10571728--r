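Package: spikequant
Title: Absolute Plasma Proteome Quantification from Spike-In DIA Transition Reports
Version: 0.1.0
Authors@R: person("Plasma", "Proteomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing pipeline for data-independent acquisition (DIA)
    targeted proteomics with stable-isotope-labeled recombinant protein
    standards spiked into plasma. Pairs light (endogenous) and heavy
    (standard) fragment-ion transitions, computes ratio-to-standard
    quantities and converts them to absolute concentrations (pmol/uL raw
    plasma), applies score/ratio/retention-time quality filters, performs
    pool-based plate median normalization, and derives assay QC statistics
    (intra-assay CV, pool correlation, normalized IQR). Downstream analysis
    includes a one-vs-rest differential-abundance screen with Bonferroni
    control and a cross-validated random-forest classifier with kNN
    imputation, ROC/AUC and 0-100 feature relevance scores. A synthetic
    cohort generator with planted ground truth (plate/pool design, lognormal
    noise, missingness, QC failures, disease effects) makes every stage
    testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
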