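Package: migsel
Title: Selective Migration and Regional Stratification of Polygenic Scores
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how internal migration restructures the
    regional distribution of polygenic scores in a national cohort. Implements
    the between-county variance-partition statistic SSB/(SSB+SSW) with ANOVA
    and joint-factor likelihood-ratio gain tests, sibship construction from
    pairwise kinship estimates with a same-birthplace rule, within-sibship
    centering and a simulation-based empirical null for the sibling design,
    a nine-group migration taxonomy with group and county mean contrasts,
    population-level and within/between-sibship logistic regression for a
    rural-to-city migration phenotype, the Robertson observed-to-liability
    heritability transformation, and a synthetic-cohort generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
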