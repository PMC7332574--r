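Package: lpm
Title: Linear Poisson Modelling of Count Histogram Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits non-negative linear mixtures of probability mass functions to
    cohorts of count histograms (e.g. imaging mass-spectrometry pixels or
    apparent-diffusion-coefficient histograms) under an extended
    maximum-likelihood Poisson model, a reformulation of probabilistic latent
    semantic analysis. Beyond the point estimates shared with pLSA/NNMF it
    provides minimum-variance-bound covariances on the fitted quantities,
    square-root-space chi-squared goodness-of-fit with effective
    degrees-of-freedom per spectrum, calibrated P-values for null-component
    hypothesis tests, the MAX SEP component-separation algorithm, Bland-Altman
    noise diagnostics, model-order selection, and a seeded Monte Carlo
    simulator of mixed-tissue histogram images for validation.
License: MIT
Encoding: UTF-8
Imports: stats, utils, MASS, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
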