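Package: cpfam
Title: Comparative Evolution of Tandemly Duplicated Cysteine-Protease Allergen Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the evolution of the papain-like cysteine-protease
    (group 1 allergen) gene family in astigmatic mites and similar tandemly expanded
    gene families. Identifies family members by local alignment and profile scoring,
    classifies tandemly and proximally arrayed genes from gene synteny, builds
    distance-based phylogenies with bootstrap support and extracts clade clusters,
    maps catalytic triads (C-H-N) and linear epitopes through multiple alignments,
    tests per-site selection with Nei-Gojobori pathway counting, quantifies transcript
    abundance in TPM from k-mer read assignment, and scores ELISA seropositivity.
    Includes a tandem-duplication genome simulator with recorded ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    phangorn,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    tidyr,
    rtracklayer,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
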