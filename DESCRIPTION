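Package: mrmediate
Title: Two-Sample and Mediation Mendelian Randomization on GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and two-step
    mediation MR on GWAS summary statistics: instrument selection
    (significance threshold, greedy LD clumping, F-statistic weak-instrument
    filtering, mediator-association exclusion), allele harmonization with
    palindromic-SNP handling, six causal estimators (Wald ratio, IVW,
    MR-Egger, weighted median, simple and weighted mode), sensitivity
    analyses (Cochran's Q, Egger intercept, leave-one-out, cross-trait
    pleiotropic-SNP filtering, reverse MR), and product-of-coefficients
    mediation with mediated-proportion inference. A seeded summary-level
    simulator generates exposure/mediator/outcome triples with known ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
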