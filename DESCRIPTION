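Package: gmtrials
Title: Simulation and Interaction-Aware Analysis of Multi-Site GM Crop Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the statistical assessment of genetically modified
    crop varieties in multi-site randomized-complete-block field trials. A
    simulator generates plot-level log-scale responses under the linear
    mixed model with site, block-within-site, genotype and site-by-genotype
    interaction effects, with the genotype roster split into the GM entry,
    its conventional comparator and a random sample of commercial reference
    varieties. A closed-form balanced ANOVA engine partitions sums of
    squares (including the site-by-test-entry and site-by-reference
    interaction components), computes exact expected mean squares and
    method-of-moments variance components, and drives both the no-interaction
    ("naive") and the interaction-aware GMO-vs-comparator difference tests,
    a genotype-by-environment interaction check, and reference-population
    equivalence testing with study-specific limits. A Monte-Carlo engine
    quantifies the type-I error inflation and power loss incurred when the
    interaction is omitted from the analysis model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
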