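Package: fstpurge
Title: FST Reduction at Selectively Constrained Sites and the Excess of
    Within-Population Deleterious Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Hudson and Nei (GST) fixation indices for classes of
    biallelic SNPs using the ratio-of-averages combination, quantifies the
    proportional reduction (rho) of FST at selectively constrained
    (nonsynonymous) sites relative to neutral (synonymous) sites, and inverts
    the theoretical rho-eta relationship to predict eta, the excess fraction
    of deleterious variants segregating within populations compared to
    between populations. Includes CADD-score binning of nonsynonymous SNPs, a
    rare-allele control filter, bootstrap standard errors with a Z-test for
    class differences, readers for VCF, sample-panel and frequency-table
    inputs, and a forward Wright-Fisher two-population simulator that
    generates panels in which purifying selection purges deleterious variants
    over divergence time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
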