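Package: smtdedup
Title: Single-Molecule-Tag Deduplication for Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies PCR duplicates in targeted amplicon deep-sequencing
    data using random single-molecule tags (SMTs, also known as unique
    molecular identifiers) carried on the index read. Assigns read pairs to
    amplicon targets by bounded-edit-distance matching of 22-bp read
    prefixes against locus-specific primers, marks duplicates by first-seen
    tag within each target, models chance tag collisions with a Poisson
    usage model and an occupancy resampling estimator, and quantifies how
    residual duplicates inflate the false positive rate of Fisher exact
    allele-frequency comparisons between samples. Ships a synthetic-data
    generator with known truth (targets, heterozygous SNPs, duplicate
    rates, tag-usage bias, sequencing error) and the sample-splitting /
    duplicate-injection simulation framework.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
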