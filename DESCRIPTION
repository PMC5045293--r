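Package: craniodigen
Title: Rare-Variant Burden and Two-Locus Linkage Analysis for Midline Craniosynostosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-genetics toolkit for digenic (rare x common variant)
    analysis of non-syndromic midline craniosynostosis cohorts. Implements
    Poisson burden tests for de novo mutations against gene- and class-level
    mutation-rate expectations, gene-length-weighted binomial burden tests for
    rare transmitted damaging variants, Fisher's-method combination of de novo
    and transmitted evidence, exact contingency statistics for two-locus
    (rare damaging allele x common risk SNP) interaction including the
    Freeman-Halton extension of Fisher's exact test, the transmission
    disequilibrium test, carrier penetrance estimation, and a parametric
    two-locus pedigree likelihood with lod scores and maximum-likelihood
    penetrance estimation. A synthetic cohort and pedigree generator
    reproduces the statistical structure the analyses assume, so the full
    pipeline runs and validates without access to restricted genotype data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
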