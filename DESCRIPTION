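Package: irswitch
Title: Detection of DNA-Polymerase Template Switching Between Inverted
    Repeats in Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting DNA-polymerase template-switching events
    between the arms of short perfect inverted repeats (IRs) in protein-coding
    genes, from per-gene codon alignments and a rooted species tree. The
    package finds perfect IRs, calls multinucleotide mutations (MNMs) on
    terminal branches from marginal ancestral reconstructions under a
    GY94-type codon model with gamma-distributed omega (M5), tests the
    IR/MNM association against a simulation-based empirical null built from
    100 constrained replicates, classifies events as arm homogenization,
    complete spacer inversion or both, and annotates the protein-level
    consequences (amino-acid replacements, Grantham distances,
    transition/transversion tallies). A synthetic-data generator with a
    ground-truth ledger of planted events supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
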