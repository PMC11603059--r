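Package: TEactivity
Title: Quantification of Transposable-Element Transcriptional Activity from
    RNA-Seq Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify transposable-element (TE) transcription across
    conditions from RepeatMasker-annotated transcriptome assemblies: parsing and
    redundancy-filtering of RepeatMasker .out annotations, assignment of mapped
    reads to TE copies under length/similarity cutoffs, percent-of-mapped-reads
    profiles by TE class and LTR superfamily, Kimura 2-parameter divergence
    landscapes of the expressed repeat fraction, single-copy-orthologue-scaled
    TPM normalization, and the associated statistical battery (Pearson
    correlation panels with a random-gene null control, one-way ANOVA with
    significance stars, mean +/- SEM summaries). A seed-reproducible synthetic
    data generator emulates stage-structured TE activity and a DNA-demethylation
    derepression contrast so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
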