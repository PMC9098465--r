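Package: metablup
Title: Metabolomic Phenotype Prediction with Kernel BLUP and Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts quantitative phenotypes from binned 1H-NMR metabolomic
    spectra. Provides spectral preprocessing (region exclusion, probabilistic
    quotient normalization, interval correlation alignment, feature
    standardization), construction of a metabolomic similarity matrix M = QQ'/m,
    restricted maximum likelihood estimation of the two-component mixed model
    y = 1mu + m + e with best linear unbiased prediction of held-out samples,
    univariate partial least squares regression (NIPALS PLS1) with inner
    leave-one-out component tuning, and three leave-set-out cross-validation
    designs (random training sets of fixed size, leave-one-line-out,
    leave-one-location-out) with plot-level and line-mean prediction accuracies.
    A synthetic generator produces plot-structured spectra and phenotypes with
    known ground truth for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
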