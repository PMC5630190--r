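Package: methmr
Title: Causal Triage of Genetic Signals Shared by DNA Methylation and
    Cardiovascular Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a genetic variant that is associated
    with both DNA methylation at a CpG site and a cardiovascular trait acts
    through mediation, reverse causation, linkage-disequilibrium confounding,
    or horizontal pleiotropy. Implements an mQTL-by-trait association scan
    with Bonferroni control, one-sample two-stage least-squares and
    two-sample Wald-ratio Mendelian randomization with delta-method standard
    errors, bivariate approximate-Bayes-factor fine mapping with a
    concordance-rate statistic, matched-resampling hypergeometric enrichment,
    and a synthetic-study generator with known causal architecture so that
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
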