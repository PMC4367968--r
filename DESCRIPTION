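Package: eyereg
Title: Regularity Analysis of the Drosophila Compound-Eye Surface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial regularity of the Drosophila compound-eye
    surface from reflected-light photographs. Ommatidial reflections are
    detected as prominence-filtered intensity maxima after rolling-ball
    background subtraction and an inverted-shift averaging filter; eighteen
    grid-based and region-based spatial regularity variables are extracted and
    converted through a built-in multinomial logistic model into a regularity
    index (IREG) between 0 (fully degenerate) and 1 (wild-type regularity).
    Includes the full model-building pipeline (correlation pruning, ANOVA
    screening, PCA-based class construction, multinomial fitting, stepwise
    selection, robustness checks), nonparametric group comparison, a synthetic
    hexagonal-lattice eye-image generator with ground truth, and a batch
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'tiff.R'
    'io-image.R'
    'io-roi.R'
    'preprocess.R'
    'maxima.R'
    'grid.R'
    'features.R'
    'model-ireg.R'
    'model-build.R'
    'model-compare.R'
    'synthetic.R'
    'pipeline.R'
    'eyereg-package.R'
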