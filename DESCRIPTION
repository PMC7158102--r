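Package: panelscope
Title: Targeted Sequencing Panel Database, Copy-Number Ratios and Plot Builders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds single-file SQLite databases for tumor/normal targeted
    sequencing panels and computes the quantities a panel reviewer inspects:
    depth-normalized copy-number ratios with configurable chromosome
    normalization, automatic per-interval and per-gene-group copy-number
    calls, FILTER-aware mutation and structural-variant tables with
    Ensembl-VEP CSQ annotation extraction, B-allele-frequency points for
    loss-of-heterozygosity review, and deterministic specifications for
    whole-genome, per-chromosome, SNP and Circos-style plots. A synthetic
    fixture generator produces complete panel inputs (BED, depth tables,
    VCFs, SNP allelic tables) with known truth so the whole pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    yaml,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
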