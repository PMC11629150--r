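Package: gbtskit
Title: SNP Panel Design, Bulked-Segregant Mapping and F2 Fine Mapping
    for Target-Capture Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building targeted genotyping (liquid-phase
    capture / GBTS) SNP panels from a population VCF and a reference
    genome, and for mapping a trait locus with the panel. Implements the
    panel-selection cascade (minor-allele-frequency and missingness
    filters, 100-bp flank extraction with GC and N rules, single-copy
    probe-context checks, functional classification against a GFF3
    annotation), the bulked-segregant (BSA-seq) Euclidean-distance
    statistic with SNP-count window fitting and candidate-interval
    calling, F2 segregation utilities (fruit-shape-index descriptives,
    3:1 chi-square test, 2^-ddCt fold change), recombinant-based fine
    mapping with promoter W-box motif scanning and allele comparison,
    and a synthetic-data generator (genome, population VCF, F2 cross,
    extreme-phenotype pools) with recorded ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
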