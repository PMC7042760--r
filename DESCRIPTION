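Package: pollinet
Title: Quantitative Plant-Pollinator Network Analysis Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing quantitative (count-valued) bipartite
    plant-pollinator interaction networks sampled along environmental
    gradients. Builds one network per transect walk from long-format
    interaction records, computes species-level specialization (d'),
    network-level complementary specialization (H2'), weighted nestedness
    (WNODF), dependence asymmetry and secondary-extinction robustness,
    standardizes indices against fixed-marginal (Patefield) null models,
    derives a composite land-use intensity index, fits the gradient stage as
    linear mixed-effects models with AICc-based predictor comparison and
    semipartial R2, and performs piecewise path analysis with d-separation
    basis sets and Fisher's C. A synthetic-study generator with known ground
    truth supports end-to-end testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
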