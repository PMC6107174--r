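Package: mfsway
Title: Multifractal Analysis of Postural-Sway Series with Surrogate Tests for Nonlinearity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Direct (Chhabra-Jensen) estimation of the multifractal
    singularity spectrum of nonnegative displacement series, iterated
    amplitude-adjusted Fourier transform (IAAFT) surrogate ensembles as the
    best-fitting linear null, and the t statistic comparing spectrum width
    against that null. Includes block-wise cohort pipelines for
    repeated-measures postural-sway designs, the two companion linear
    mixed-effects models (smooth polynomial and categorical block codings
    with a per-subject random intercept), and a synthetic-data generator
    built on binomial multiplicative cascades so the full chain can be
    validated against closed-form spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
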