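Package: lffpipe
Title: Low-Frequency Fluctuation Analysis with Nuisance-Regression Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise spectral amplitude measures for resting-state BOLD
    fMRI (ALFF, fALFF and the high-frequency variant hfALFF) together with
    the nuisance-regression machinery needed to study how preprocessing
    choices affect them: polynomial and exploratory (lag-one CCA) detrending,
    PCA-based white-matter and CSF tissue regressors, realignment-parameter
    regression, QR orthogonalisation of regressor blocks, phase-randomised
    surrogate controls, and Fourier-domain least squares. Includes a
    multi-subject, multi-session synthetic BOLD generator with ground truth,
    group-level t and test-retest variance statistics, and a runner that
    evaluates all sixteen regressor-block combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
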