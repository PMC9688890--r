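Package: thalnet
Title: Intrinsic Thalamic Structural Covariance Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares group-level structural covariance networks of
    the 50 thalamic nuclei (25 per hemisphere) from tabular volumetry. Starting
    from a per-subject cohort table of absolute nucleus volumes and covariates,
    the package normalizes volumes by estimated total intracranial volume,
    residualizes age, sex and lesion load, forms per-group inter-nucleus
    correlation matrices, binarizes them over a sparsity grid, computes
    small-world, efficiency and nodal graph metrics with degree-preserving
    randomized nulls, summarizes metric curves by their area under the curve,
    and tests group differences with permutation tests and Benjamini-Hochberg
    false discovery rate control. A synthetic cohort generator with block
    covariance structure and plantable network effects supports calibration
    and power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml
Config/testthat/edition: 3
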