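Package: panins
Title: Breakpoint-Resolved Non-Reference Insertion Discovery and Population
    Genotyping for Cattle Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pangenome analysis toolkit for Bos indicus cattle.
    Discovers breakpoint-resolved non-reference unique insertions (NUIs) from
    pseudohaplotype assemblies and short reads by an alignment-cluster method
    and by incremental augmentation of a multi-assembly graph, intersects the
    two call sets with best bidirectional hits, genotypes insertions across a
    read cohort to derive common insertions (BICIs) by minor-allele-frequency
    filtering, and characterizes them by repeat content, genic context,
    population structure (PCA and hierarchical clustering) and cross-species
    sharing. Ships a fully truth-annotated synthetic cohort generator
    (reference, repeat library, insertions, diploid genotypes, pseudohaplotype
    assemblies, paired reads) so the whole workflow runs without downloads,
    plus a k-mer seed-chain-extend alignment engine, MinHash/Mash distances,
    and a symmetric DUST low-complexity masker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    ape,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
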