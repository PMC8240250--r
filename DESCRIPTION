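Package: falsitronr
Title: Detection of Reverse-Transcription Splicing Artifacts in Long-Read RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies "falsitrons" - apparent exitron-like splice junctions
    that are supported only by reverse-transcription-based long-read protocols
    (cDNA-seq, direct cDNA-seq) and absent from direct RNA sequencing of the
    same sample, a signature of reverse-transcriptase slippage between direct
    repeats rather than genuine splicing. Provides a filter cascade over paired
    cDNA/dRNA spliced alignments, a direct-repeat k-mer search at splice-site
    windows, relative-abundance estimators for long- and short-read data, a
    shift-tolerant junction matcher for external junction tables, position-wise
    splice-site nucleotide profiles, and a synthetic-data generator that plants
    RT-slippage loci with known truth for end-to-end validation. All user-facing
    functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
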