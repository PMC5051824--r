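Package: fastxkit
Title: Tidy Toolkit for FASTA and FASTQ Manipulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comprehensive toolkit for FASTA/FASTQ file manipulation built
    around a tibble of sequence records. Provides a streaming parser for plain
    or gzip-compressed FASTA/FASTQ (multi-line records, standard streams,
    format and sequence-type autodetection, custom ID patterns), a FASTA index
    for random access and memory-bounded two-pass processing, and nineteen
    operations covering transformation (reverse complement via a 256-slot byte
    lookup table, transcription, case folding, validation), subsequence
    extraction (negative-coordinate regions, GTF/BED features with strand-aware
    flanks, sliding windows), searching (record filtering and IUPAC degenerate
    motif location), set operations (digest-based deduplication, common
    records, splitting, seeded sampling), editing (regex replace, duplicate-ID
    renaming) and ordering (seeded shuffling, natural-order sorting). A single
    command-line entry point exposes every operation for use in shell
    pipelines; a deterministic fixture generator produces test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stringr,
    tibble,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
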