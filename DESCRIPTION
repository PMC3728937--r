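Package: gencline
Title: Genomic Cline Models, Multivariate Outlier Detection and Hybrid Zone
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic cline analysis of hybrid zones and admixed
    populations. Fits three two-parameter cline models (logit-logistic,
    regularized incomplete beta, and the spliced Barton polynomial) plus
    binomial and multinomial logistic regression baselines to counts of
    ancestry-diagnostic alleles by maximum likelihood under a
    product-of-binomials likelihood, compares models with AICc, tests the
    naive null hypothesis p = S by likelihood ratio, and screens for loci
    under selection with multivariate (Mahalanobis / chi-squared) outlier
    detection that is robust to genetic drift.  Includes a stochastic
    individual-based simulator of secondary contact in continuous
    two-dimensional space with density-dependent reproduction, four modes
    of selection (environmental gradient, heterozygote advantage or
    disadvantage, and Dobzhansky-Muller incompatibilities), and open or
    closed boundaries, together with a study harness that scores outlier
    detection performance on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
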