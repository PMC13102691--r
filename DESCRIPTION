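Package: lifegrad
Title: Lifespan Functional Connectivity Gradients: Embedding, Alignment,
    Trajectories and Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a lifespan cortical-gradient
    pipeline: Pearson functional connectivity, row-wise thresholding,
    normalized-angle affinity kernels and diffusion-map embedding;
    weighted-PCA lifespan gradient templates with one-shot Procrustes
    alignment; scalar and network-level gradient metrics (dispersion,
    inter-vigintile axis ranges, template cosine similarity, network
    centroids and distances); harmonized penalized-spline lifespan
    trajectory models with random intercepts, density weighting,
    nonlinearity testing, posterior peak-age intervals and sex-deviation
    models; and downstream association stages (behaviour regressions,
    meta-analytic term axes, permutation-tested one-component PLS
    transcriptomic enrichment). A synthetic cohort generator plants
    known lifespan laws so every stage is testable without restricted
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmerTest,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
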