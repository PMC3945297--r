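Package: somaselect
Title: Selection on Somatic Substitutions in Tumors via dN/dS and
    Functional-Site Ratios
Version: 0.1.0
Authors@R:
    person("somaselect", "developers", email = "somaselect@example.org",
           role = c("aut", "cre"))
Description: Quantifies natural selection acting on somatic substitutions in
    tumor cohorts and on germline variants. Implements unweighted (Nei-Gojobori
    style) counting of non-synonymous and synonymous sites per coding
    transcript, partitioning of missense changes into more-functional and
    less-functional classes under SIFT-like score tables and PolyPhen-like
    class tables, MAF-style somatic substitution parsing with within-tumor
    deduplication and nonsense/frameshift gene inactivation filtering,
    germline allele-frequency filtering, expression-breadth classification of
    genes across 16 tissues, pooled dN/dS and dMF/dLF ratio statistics with
    chi-square tests against neutrality, site-composition-corrected group
    comparisons, per-gene positive-selection screens, gene-set enrichment
    tests, a fully seeded synthetic-data generator emulating tumor cohorts and
    germline panels, and an end-to-end pipeline with a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
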