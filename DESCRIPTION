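Package: clipsplice
Title: Binding-Site Definition and Alternative Splicing Analysis for Plant iCLIP Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the binding landscape of an RNA-binding protein,
    mapped by individual-nucleotide resolution crosslinking and immunoprecipitation
    (iCLIP), to alternative-splicing outcomes. Per-nucleotide crosslink peaks are
    deduplicated, merged and extended into 9-nt binding sites with control-sample
    subtraction; sites are assigned to transcript features and profiled relative to
    transcription start sites and 5' splice sites; hexamer enrichment is scored
    against a transcript-matched resampled background; alternative-splicing events
    (alternative acceptor/donor, cassette exon, retained intron, exitron) are
    enumerated from annotation and quantified as percent-spliced-in with a Beta
    posterior on pooled junction counts; gene-set overlaps are tested with the
    hypergeometric distribution and summarised by a representation factor. A
    synthetic-data module generates genomes, annotations, crosslink peaks and
    junction counts with known ground truth so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
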