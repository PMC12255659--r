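Package: qsmrep
Title: Repeatability Analysis for Quantitative Susceptibility Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Test-retest repeatability analysis for repeated quantitative
    susceptibility maps (QSM). Provides voxel-wise similarity metrics (NRMSE
    and XSIM, a structural-similarity variant suited to signed susceptibility
    data), ROI-level variance decomposition (within-region, within-subject and
    between-subject standard deviations, coefficient of variation, one-way
    intraclass correlation with bootstrap confidence intervals, repeatability
    coefficient), and repeated-measures ANOVA with Mauchly's sphericity test
    and lower-bound degrees-of-freedom correction. A synthetic multi-subject,
    multi-repetition cohort simulator with k-space dipole-field physics (TKD
    and Tikhonov closed-form inversions, multi-echo gradient-echo signal
    generation and field-map fitting) supplies ground truth so that every
    statistic can be validated end to end without acquired MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
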