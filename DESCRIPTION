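Package: dynqtl
Title: Dynamic Multi-Family QTL Mapping Across Developmental Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTL) whose effects
    change over developmental time in multi-parent populations of doubled
    haploid (DH) lines. Provides a simulator for partially connected
    multi-family DH populations with time-indexed QTL architectures,
    computation of best linear unbiased estimates (BLUEs), variance
    components and entry-mean heritability from multi-environment trials,
    multi-family association scans with stepwise cofactor selection and
    Bonferroni-Holm correction, two-dimensional epistasis scans with a
    region-pair Bonferroni threshold, accounting of the proportion of
    genotypic variance explained by detected QTL, fivefold cross-validation
    of the detection pipeline, and a dynamic layer that matches QTL across
    stages, builds Venn partitions, scans developmental-progression traits
    and reports sign changes of allele-substitution effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
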