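Package: regulomap
Title: Functional Fine-Mapping of a Regulatory GWAS Risk Locus Under Aneuploidy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis pipeline for post-GWAS functional fine-mapping
    of a regulatory risk locus in a hyperdiploid leukaemia setting. Implements
    per-SNP additive logistic association and fixed-effects inverse-variance
    meta-analysis, LD-based risk-haplotype selection and regulatory-annotation
    prioritisation, allele-specific transcription-factor-binding tests from
    masked-reference alignments with (weighted) Fisher combination across
    replicates, Knight-Ruiz balancing of binned chromatin contact matrices
    with observed/expected loop enrichment and TAD-contained anchor profiles,
    trisomy-restricted eQTL ANOVA, B-allele-frequency classification of the
    duplicated homologue, and the one-sided binomial preferential-retention
    test. A synthetic-data module generates every input with a known truth
    ledger so the whole chain is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
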