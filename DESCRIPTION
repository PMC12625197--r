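Package: NPQtools
Title: Quality Control, Differential Abundance and Biomarker Cutoff
    Analysis for Targeted Plasma Proteomic Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of targeted plasma proteomic panels
    reported on the log2 NPQ (NULISA Protein Quantification) scale, as
    used in mixed-dementia biomarker studies. Implements IQR outlier
    masking and two-step call-rate filtering, the NPQ normalization
    chain (log2 to linear to log10 to z-score), surrogate-variable
    adjusted per-protein differential abundance with
    Benjamini-Hochberg control, cross-disease effect-size z-tests,
    correlation, clustering and scorecard ranking, data-driven
    biomarker positivity cutoffs (two-component Gaussian mixture
    crossing, Youden index, dual 95 percent sensitivity/specificity
    thresholds) with concordance evaluation against amyloid-PET style
    references, DeLong ROC analysis, Kruskal-Wallis/Dunn group tests,
    over-representation statistics, and Cox proportional-hazards
    progression analysis. A synthetic cohort generator emulating the
    statistical structure of such studies makes every stage testable
    without access to restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    sva,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, QualityControl, Normalization, Regression,
    Classification, Survival
RoxygenNote: 7.3.3
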