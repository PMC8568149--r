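Package: methtrace
Title: Import, Storage and Visualization of Long-Read Methylation Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-read 5mC methylation calls produced by the nanopore
    methylation callers nanopolish, f5c and Megalodon into a sorted,
    bgzip-compressed, tabix-indexed tabular store supporting fast genomic
    region queries; aggregates calls into site-by-sample count matrices and
    exports the input formats of differential-methylation tools (bsseq, DSS,
    edgeR styles); and builds sample embeddings (MDS, PCA) on
    log-methylation-ratio matrices, metagene-style aggregate profiles over
    scaled feature bodies with fixed-width flanks, and per-read region views
    (spaghetti and heatmap plots) with exon tracks, CpG ticks and DMR shading.
    Includes a seeded synthetic-data generator that emits caller-format files
    with known per-site methylation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
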