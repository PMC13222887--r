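Package: sfgc
Title: Structural-Functional Gradient Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying the coupling between structural
    and functional connectivity gradients of the cortex. Builds diffusion-map
    gradients from dense connectomes (proportional thresholding, cosine
    affinity, anisotropic Markov normalization, Procrustes template
    alignment), quantifies structural-functional gradient coupling at the
    macroscale and within subnetworks as pairwise cosine similarity,
    harmonizes features across sites and studies with an empirical-Bayes
    location/scale model and a bridging-cohort offset, predicts behavioral
    outcomes out of sample with family-aware kernel ridge regression and a
    compact feed-forward network including normalized feature importance,
    estimates ACE twin heritability with a boundary-corrected likelihood
    ratio test and power simulation, performs spin-rotation spatial
    inference, and relates regional heritability maps to gene expression
    via Spearman ranking and set enrichment against a spin null. A
    synthetic-data module generates every input with known ground truth so
    the whole pipeline is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    sva,
    vegan,
    pROC,
    optparse
Config/testthat/edition: 3
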