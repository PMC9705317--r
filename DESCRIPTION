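Package: minpop
Title: Population Genomics of Structured Anopheles Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled toolkit for whole-genome population genomics of
    structured mosquito cohorts, modelled on the analysis of Anopheles minimus
    in Cambodia. Provides a Balding-Nichols cohort simulator (reference FASTA,
    GFF3 gene models, multi-sample VCF, metadata and ground truth), sample and
    site quality control with a site-class census, PCA-based population
    structure with iterative outlier exclusion and mislabel flagging,
    degeneracy-aware diversity statistics (nucleotide diversity, Watterson's
    theta, Tajima's D) with sample-bootstrap confidence intervals, windowed
    Hudson Fst genome scans with selection-signal detection and candidate-gene
    annotation, and per-population allele-frequency reports for
    insecticide-resistance genes.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
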