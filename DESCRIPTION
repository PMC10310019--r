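Package: gutbrainmst
Title: Diet-Linked Connectivity of Gut Microbiota and Brain Cortex Networks via Minimum Spanning Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how animal protein and lipid intake relates to the
    connectivity of two biological networks in children: a brain-cortex-activity
    network built from bias-corrected mutual information between qEEG region-of-
    interest band powers, and a gut-microbiota network built from probabilistic
    (hypergeometric) ASV co-occurrence. Connectivity is summarised as the total
    weight of the minimum spanning tree, compared between high- and low-intake
    groups, and calibrated against a random-subnetwork null model. Includes
    food-frequency intake estimation, qEEG band-power extraction, rarefaction and
    alpha diversity, random-forest Gini screening of ASVs, and seeded synthetic
    generators for EEG, ASV tables and food-frequency records.
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
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
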