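Package: phyloskim
Title: Genome-Skimming SNP Supermatrix Phylogenomics and Ancestral State
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a reference-based
    genome-skimming SNP workflow for plant phylogenomics: reciprocal-best-hit
    selection of one-to-one orthologues from tabular similarity hits, a
    median-relative coverage and quality filter cascade on genotype tables,
    minor-allele sharing and biallelic filters, missing-data gradient scans,
    SNP supermatrix and per-gene matrix assembly, tree post-processing
    (support-based branch collapsing, Robinson-Foulds distances,
    representative-topology selection, neighbour-joining from alignments with
    pairwise deletion), and maximum-likelihood ancestral state reconstruction
    of discrete morphological characters under Mk models, including leaf-size
    discretisation. A synthetic-data module simulates species trees, diploid
    biallelic SNP genotype tables with realistic depth, quality and
    missingness structure, and discrete characters evolved under
    continuous-time Markov models, so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    tools,
    utils,
    vcfR,
    withr
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
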