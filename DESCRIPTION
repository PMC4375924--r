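Package: decoupleage
Title: mRNA/Protein Expression Decoupling over Brain Development and Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and classifies the coupling between mRNA and protein
    expression trajectories over a primate lifespan. Provides label-free
    proteomic (NSAF) and RNA-seq (RPKM/TPM) quantification with reliability
    filters, polynomial age-trajectory model selection on a fourth-root age
    scale, spline interpolation onto uniform developmental and aging grids,
    exact-permutation Spearman concordance classification with a re-pairing
    permutation FDR, consensus k-means expression patterns, CLIP-derived RNA
    binding protein binding-site enrichment, and seed-level miRNA target
    enrichment with a correlation-shift estimator of translational
    repression. Includes a seeded synthetic-data generator that plants
    concordant and discordant mRNA/protein structure so the whole pipeline
    can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
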