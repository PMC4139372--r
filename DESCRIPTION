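Package: antnet
Title: Bipartite Ant-Plant Interaction Networks and Ant-Exclusion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bipartite ant-plant interaction networks built
    from extrafloral-nectary visitation records, and for the outcome statistics
    of ant-exclusion herbivory experiments. Computes network descriptors
    (species degree, connectance, web asymmetry), NODF nestedness with a
    Monte-Carlo significance test under the probabilistic Ce (type II) null
    model, and the network-level specialization index H2' with its entropy
    bounds. Aligns two temporal snapshots of a network, quantifies species
    turnover and degree change, and compares degree distributions with a
    two-sample Kolmogorov-Smirnov test. Analyses factorial ant-exclusion
    experiments (species x stem treatment x year ANOVA, Tukey post hoc,
    per-species t-tests with Bonferroni correction, paired tests of
    log-transformed ant abundance) and ships seeded generators for synthetic
    networks and herbivory data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
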