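Package: spatfield
Title: Spatial Models for Agricultural Field Trials with Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates wheat-like breeding programmes and field trials, and fits
    Bayesian latent Gaussian models with independent row-and-column, separable
    AR1xAR1, or Matern Gaussian random field spatial effects, with or without
    genome-wide marker effects (VanRaden genomic relationships, singular value
    decomposition marker compression). Inference uses exact conditional
    posteriors for the Gaussian likelihood with hyperparameter posterior
    exploration (empirical Bayes, grid, or CCD-style integration). Model
    comparison uses the continuous ranked probability score, correlation with
    true breeding values, and top-individual capture. Includes irregular
    layouts such as the Nelder wheel spacing-trial design and a finite element
    (SPDE) approximation to the Matern field.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
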