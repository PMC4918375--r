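Package: iclipfrag
Title: Fragment-Length Diagnostics and Binding-Site Assignment for iCLIP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to diagnose whether the start or the centre position of
    sequenced iCLIP fragments gives the more accurate assignment of
    protein-RNA crosslink sites. Classifies reads by 3' adapter content into
    completely sequenced (group A) and length-censored (group B) fragments,
    deduplicates alignments by random barcode, builds junction-anchored read
    distribution maps and length-stratified heatmaps, computes annotation-free
    read overlap heatmaps and the start site overlap ratio, profiles base
    composition around fragment boundaries, and ships a mechanistic iCLIP
    library simulator (reverse-transcriptase truncation and read-through,
    RNase footprint protection, PCR duplication) with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
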