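Package: strainforge
Title: Multiplex Microbial Resequencing, Structural Variant Discovery,
    and Iterative Genome Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless analysis engine for multiplex microbial
    whole-genome resequencing and genome engineering. Aligns short reads
    to a reference genome, calls single-nucleotide variants with a
    diploid-mode pileup genotyper that reports a wild-type / marginal /
    mutant evidence trichotomy (GT_TYPE), discovers structural variants
    (deletions, novel-sequence insertions, and mobile-element
    translocations) by local de novo assembly of candidate reads and
    traversal of a contig-to-reference placement graph, and detects large
    deletions from coverage. Variant evidence across samples is stored in
    a denormalized variant-by-sample table queryable with a Boolean
    key-value language in melted or cast views. Variant sets drive
    reference-genome versioning with annotation lift-over (iterated until
    no further variants are called) and the design of multiplex
    recombineering (MAGE) oligonucleotides targeting the lagging strand
    of each replichore. A seeded simulator generates annotated genomes,
    mutant derivatives with a recorded truth table, and error-bearing
    paired-end reads so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
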