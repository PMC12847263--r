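Package: dmdbold
Title: Dynamic Mode Decomposition Features for Resting-State fMRI ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extracts per-region mean mode-amplitude features from regions-of-interest
    BOLD time series via exact dynamic mode decomposition (DMD) with scaled modes,
    in the full infra-slow band (0.01-0.1 Hz) and in equal-width sub-bands.
    Identifies group-discriminative "abnormal" regions by intersecting repeated
    LASSO selections and screening the intersection with label-permutation tests,
    benchmarks feature sets with cross-validated linear support vector machines,
    and exposes DMD signal reconstruction/prediction plus the comparison of the
    mode-sequence correlation matrix (phiC) with functional connectivity (FC).
    Includes a synthetic-cohort generator with planted band- and region-specific
    group effects for validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
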