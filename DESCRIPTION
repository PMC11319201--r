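Package: xclonal
Title: X-Linked Clonal Diversity, Inactivation Skew and Clonal Proportion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the genetic diversity that random X-chromosome
    inactivation exposes within XX individuals, and for testing whether the two
    resulting clonal compartments are equally represented. Computes pairwise
    missense-difference distributions between phased X haplotypes with
    consequence filtering and escape-gene masking; converts allele-specific
    qPCR threshold-cycle measurements or allele-specific read counts into
    variant-clone fractions with a fitted calibration model and tests departure
    from the 50 percent expectation; tests per-cluster cell-proportion shifts
    between genotypes by label-permutation with bootstrap intervals and
    Benjamini-Hochberg false-discovery control; scores cells against a gene set
    by an area-under-recovery-curve statistic; and provides a stochastic
    founder-cell sampling null for X-inactivation skew together with a
    moment-based founder-number estimator. A synthetic-data layer generates
    phased cohorts, qPCR panels, cluster counts and ranked expression matrices
    with known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
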