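Package: tlpcensus
Title: Census, Classification and Phylogeny of Thaumatin-Like Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide censuses of the thaumatin-like
    protein (TLP, PR-5) family. Delimits the thaumatin domain with its conserved
    N- and C-terminal boundary motifs, filters incomplete domains, classifies
    architectures (typical TLP, small-TLP, TLP-kinase, small-TLP-kinase), scores
    conservation of the acidic-cleft REDDD residues, computes molecular weight
    and isoelectric point, builds Poisson-corrected Neighbour-Joining trees with
    bootstrap supports, and analyses tandem gene clusters and transposable-element
    coverage at family loci. Ships seeded generators for synthetic proteins,
    alignments evolved along a known tree, and toy genomic loci, so every stage
    is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
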