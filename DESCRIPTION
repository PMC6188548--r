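Package: subterra
Title: Branch-Site Selection Tests and Convergent Substitution Screens on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-scale screen for parallel molecular adaptation across
    independent lineages, built around two estimators: the branch-site codon
    model (Model A) with its 1-df likelihood ratio test and empirical-Bayes
    identification of positively selected sites, and posterior probabilities
    of parallel/convergent amino-acid substitutions between branch pairs
    derived from Dayhoff-model ancestral reconstructions. Includes alignment
    quality-control gates, gene-set intersection exact tests, topology-aware
    GO enrichment (classic/elim/weight), a selection-by-convergence
    co-occurrence analysis, and a codon sequence simulator with site-class
    mixtures and injected convergent sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
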