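Package: pausescape
Title: RNA Polymerase II Promoter-Proximal Pausing Analysis from ChIP-seq and PRO-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies RNA polymerase II promoter-proximal pausing and
    pause-release from aligned ChIP-seq and PRO-seq tags. Implements
    strand-aware TSS and gene-body region definition from gene annotations,
    assay-specific tag processing (150 bp fragment extension for ChIP-seq,
    1 bp reduction with the antisense-strand convention for PRO-seq),
    per-10-million-read normalization, binned TSS signal matrices and
    bedGraph export, a genome-wide Poisson-background FDR threshold and
    windowed peak caller, pausing-index computation and gene grouping,
    transcription-factor occupancy dynamics with an exact-binomial
    dismissal test, FPKM-based expression response classes under
    stimulation and knockout, and binomial promoter motif enrichment.
    Ships a seeded multi-assay synthetic data generator with per-gene
    ground truth so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
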