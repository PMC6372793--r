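Package: zerogrowth
Title: Genome-Centric Transcriptional Activity Analysis of Rare Microbial
    Populations at Zero Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and classify the transcriptional activity of
    low-abundance ("rare biosphere") microbial populations that remain at
    stable population size, from genome-centric metatranscriptomes.
    Implements FPKM and size-factor normalization of gene-by-sample count
    matrices, per-gene Spearman activity-correlation screening against
    total mRNA with Benjamini-Hochberg false-discovery control,
    negative-binomial moment/Wald differential expression with
    correlation-distance response-group clustering, a stable-isotope-probing
    differential-coverage transform and bin gating, homology-threshold
    annotation calls, rrn-corrected population quantification, and a
    temperature-corrected Herbert-Pirt maintenance-energy budget.  A
    negative-binomial simulator with planted activity structure makes every
    stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    GenomicRanges,
    IRanges,
    mclust,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
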