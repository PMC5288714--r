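Package: rrbspipe
Title: Reduced-Representation Bisulfite Sequencing Simulation and
    Differential Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for reduced-representation bisulfite
    sequencing (RRBS) data: in-silico MspI/TaqI double digestion of a
    reference genome, construction of bisulfite-converted (three-letter)
    fragment indices, a ground-truth bisulfite read simulator with planted
    differentially methylated regions, read trimming and bisulfite-aware
    ungapped alignment with a second-best uniqueness rule, per-cytosine
    methylation calling with coverage filtering and conversion-rate
    estimation, windowed differentially-methylated-region detection by
    Fisher's exact test with Benjamini-Hochberg FDR and effect-size
    thresholds, replicate-consensus intersection and merging, and
    promoter/genic/intergenic annotation with gene-list overlap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
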