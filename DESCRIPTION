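Package: pdrc
Title: Gene-Level Population Differentiation Tests for Rare and Common
    Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level tests of population differentiation that combine
    rare and common single-nucleotide variants through weighted
    generalized Cochran-Mantel-Haenszel statistics.  Each variant in a
    gene contributes a population-by-allele contingency table; tables are
    combined with equal, inverse minor-allele-frequency (MAF), or inverse
    squared-MAF weights, yielding a chi-square distributed gene statistic
    that is sensitive to differentiation carried by rare alleles.  The
    package also provides per-variant and multi-locus Weir-Cockerham
    fixation index estimates, weighted Mantel-Haenszel odds ratios
    contrasting each population against a baseline population, variant
    selection strategies, an end-to-end gene scan with Bonferroni and
    empirical-percentile decision rules, and a seed-deterministic
    multi-population cohort simulator (Balding-Nichols differentiation,
    configurable site-frequency spectra, block linkage disequilibrium)
    with type-I-error and label-permutation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'fst.R'
    'gcmh.R'
    'genotype-io.R'
    'mh-odds.R'
    'pdrc-package.R'
    'scan.R'
    'simulate.R'
    'variant-select.R'
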