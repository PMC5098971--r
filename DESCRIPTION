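Package: ceact
Title: Comparative Expression Analysis on Consensus Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free differential transcript expression between two
    independently assembled transcriptomes of closely related populations.
    Homologous transcript pairs are found by exact Smith-Waterman local
    alignment with Karlin-Altschul e-values, reciprocal-best pairing builds a
    conversion table, and the highest-scoring alignment window is extracted
    from both members to form two paired consensus transcriptomes. Reads are
    quality-trimmed, split into 40-60 nt fragments, and mapped in four rounds
    (each population's fragments on each consensus set) with a
    mismatch-tolerant ungapped seed mapper; per-pair RPKM values are averaged
    per population and classified by log2 fold-change. Includes six-frame
    longest-ORF extraction, assembly QC statistics (N50, remap fraction), and
    a 454-style read simulator producing diverged transcriptome pairs with
    known expression ratios for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'ceact-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'seqio.R'
    'homology.R'
    'fragmap.R'
    'quant.R'
    'orf.R'
    'synthetic.R'
    'pipeline.R'
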