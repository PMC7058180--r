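Package: reqtl
Title: RNA-Level Expression Quantitative Trait Locus (ReQTL) Mapping from
    Variant Allele Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies correlations between expressed single-nucleotide
    variants and gene expression using RNA-seq data alone. Estimates the
    variant allele fraction (VAF_RNA = n_var / (n_var + n_ref)) at a list of
    SNV positions from coordinate-sorted alignments with configurable read
    filters and a minimum-coverage rule, assembles filtered VAF and
    quantile-transformed expression matrices, and tests every SNV-gene pair
    with a covariate-adjusted linear model, annotating associations as cis or
    trans and controlling the false discovery rate separately within each
    family. A genotype mode (allele counts 0/1/2 mapped to fractions
    0/0.5/1) permits side-by-side eQTL comparison, and a seeded simulator
    generates fully synthetic alignments, counts, expression, genotype and
    covariate inputs with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
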