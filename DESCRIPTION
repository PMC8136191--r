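Package: selsig
Title: Lineage-Specific Selection Signatures in Mitochondrial
    Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for contrasting molecular evolution between
    ecologically defined foreground lineages (for example subterranean
    rodents) and background lineages on a fixed phylogeny, built around a
    mitochondrial protein-coding gene such as cytochrome b.  Maps codon
    substitutions onto branches by parsimony, contrasts synonymous and
    nonsynonymous substitution densities per site and per protein domain
    with exact tests and Holm correction, scores the physicochemical
    radicality of amino-acid replacements with sliding-window z-scores,
    detects convergent replacements across phylogenetically independent
    foreground lineages, and fits branch-class codon models (M0, b_free,
    b_neut) by maximum likelihood with likelihood-ratio tests.  Includes a
    Gillespie codon-sequence simulator emitting true substitution
    histories so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
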