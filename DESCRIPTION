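Package: hennet
Title: Human-Edible Nutrient Supply Accounting and Bayesian Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for global food-system analysis: a
    four-tier mass balance of agricultural food supplies (raw plant production;
    after losses and net trade; after waste; after livestock products and feed),
    population-weighted nutrient requirement and sufficiency accounting with
    excess/deficit requirement-year headcounts, and a score-based Gaussian
    Bayesian-network analysis (hill climbing with BIC, bootstrap arc-strength
    model averaging, Markov blankets, local linear models) relating per-capita
    food production, nutrient supplies, greenhouse-gas emissions, and
    agricultural water use. Includes a synthetic-world generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
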