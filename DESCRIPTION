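Package: sceneBayes
Title: Sequential Bayesian Modelling of Image-Scene Recognition Under
    Graded Naturalness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling yes/no scene-recognition behavior when
    images are presented in sequences of gradually changing naturalness.
    Implements a sequential Bayesian observer whose recognition posterior
    blends the current image likelihood with the carried-over prior via a
    persistence weight, grid-search maximum-likelihood estimation of the
    observer's threshold and persistence hyperparameters with BIC-based
    comparison of four model variants, model-based trial-wise regressors
    for parametric fMRI analyses (likelihood certainty, prior certainty,
    Bayesian surprise) with serial orthogonalization and BIDS-style events
    export, behavioral summaries (recognition-rate curves, response
    transition proportions, paired Wilcoxon tests with Bonferroni
    correction), fixation-density maps by anisotropic Gaussian kernel
    density estimation compared via mean squared error, a spectral
    image-complexity feature, and seeded synthetic generators for
    behavioral cohorts, gaze scanpaths and image families so the full
    pipeline runs without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
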