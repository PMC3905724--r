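Package: isoshare
Title: Haplotype Sharing and Rare-Variant Association in Population Isolates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying rare variants that have drifted to elevated
    frequency in isolated populations. Provides a forward-in-time simulator of
    founder isolates with recombination on a genetic map, staged genotype
    quality control, lipid-trait derivation and transformation, kinship-aware
    linear mixed-model association with likelihood-ratio tests, detection of
    maximal haplotype identity via a surrogate-parent Viterbi hidden Markov
    model, and variant-level statistics (allele frequencies, exact
    Hardy-Weinberg tests, EM-based linkage disequilibrium, pairwise identity
    by descent, Fisher meta-analysis, power and allele-age calculations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
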