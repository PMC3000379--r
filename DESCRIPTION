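Package: gedt
Title: Grammatical Evolution Decision Trees for Detecting Gene-Gene Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evolves ternary decision trees over bi-allelic SNP genotypes with
    grammatical evolution to detect gene-gene interactions (epistasis) in
    case-control association data. Provides the grammatical evolution engine
    (binary genomes, codon transcription, MOD-rule mapping with wrapping,
    sensible initialization), an island-model genetic algorithm with
    balanced-accuracy fitness, 10-fold cross-validation with cross-validation
    consistency, a random-search negative control, a greedy gain-ratio
    (C4.5-style) baseline with subtree-replacement pruning, a two-locus
    penetrance-model simulator (XOR, BOX and MOD patterns solved to target
    heritabilities under Hardy-Weinberg genotype frequencies), and a power
    estimation harness with conservative and liberal success definitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
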