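Package: cleftsift
Title: Pedigree-Aware Rare-Variant Prioritization for Familial Orofacial Clefts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Family-based prioritization of rare coding variants from
    multi-sample annotated VCFs, as used in whole-exome studies of
    multiplex nonsyndromic orofacial cleft (NSOFC) pedigrees. Implements an
    inheritance-model-aware filtering cascade (population-frequency
    thresholds per autosomal dominant/recessive model, protein-altering
    consequence whitelist, per-pedigree Mendelian segregation, curated
    phenotype-relevance gene screen), an ACMG-style five-tier classifier
    driven by annotation-derivable evidence codes, cohort-level gene and
    pathway contribution summaries, and a gene-dropping simulator that
    generates pedigrees, Hardy-Weinberg founder genotypes, Mendelian
    transmissions and planted causal variants so the whole pipeline is
    testable without access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
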