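---
title: "fastxkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fastxkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastxkit)
```

## What the package is

fastxkit is a toolkit for everyday FASTA/FASTQ manipulation — converting,
searching, filtering, deduplicating, splitting, shuffling, sampling — built
around a single container: a tibble with one row per record and columns
`id`, `header`, `seq`, `qual` (`qual` is `NA` for FASTA). Every verb takes
that tibble first and returns one, so operations chain with the pipe;
`exec/fastxkit` exposes the same verbs as nineteen shell subcommands that
compose over standard streams. This vignette records the methods, the
defaults and why they are what they are, and the choices made where more
than one reasonable design existed.

## Parsing model

The parser is a pull-based streaming reader over a text connection: it
yields one record at a time and never retains earlier records, so `stat`
and `head` on a file path complete without materialising the file (a
`head` stops consuming the stream after its n-th record — the test suite
verifies this by placing a malformed record *after* the head window).
`read_fastx()` drains the same reader into a tibble; once you hold the
tibble you have, by construction, chosen to keep all records in memory.

Format is autodetected from the first record delimiter (`>` FASTA, `@`
FASTQ); sequence type (DNA/RNA/protein) from the leading letters of the
first record, capped at 10,000 letters — the cap is a choice, large enough
that a genome-scale first record is classified from a negligible prefix.
The rule is: all letters in the nucleic IUPAC set without `U` is DNA, with
`U` and no `T` is RNA, anything else protein.

Dialect decisions, made once:

* the record ID is the first whitespace-delimited token of the header,
  overridable with any one-capture-group regular expression (`--id-regexp`);
* multi-line sequences and multi-line FASTQ qualities are concatenated on
  input; a FASTQ record whose quality length differs from its sequence
  length is a hard error naming the record;
* text after the FASTQ `+` separator is ignored on read and written bare;
* FASTA output wraps at 60 bases (the ubiquitous convention; `0` disables),
  FASTQ output is always four lines per record — accepting multi-line FASTQ
  while never producing it is asymmetric but safest for downstream tools;
* CRLF is stripped on read, LF written; empty input is valid everywhere and
  produces empty output;
* GC% of an empty sequence is defined as 0 (avoids 0/0), and `S` (C or G)
  counts toward GC.

gzip input is detected from the two magic bytes `1f 8b`; local files
stream through `gzfile()`. Standard input is buffered fully before
sniffing, because an R connection cannot be rewound — with `-` the memory
bound is therefore the stream size, not one record; files do not pay this
cost.

## Reverse complement

Complementation uses a fixed 256-slot byte table indexed by ASCII code:
slot `code(b)` holds the complement of letter `b`, all other slots hold the
null byte, and any sequence byte landing on a null slot raises an error
naming the byte and its position. This gives constant-time per-base mapping
with strict validation for free. Three choices worth recording:

* lowercase letters map to lowercase complements — lowercase is commonly
  soft-masking and must survive a strand flip;
* the eleven IUPAC degenerate codes are complemented (R↔Y, K↔M, B↔V, D↔H,
  S, W, N self-paired) rather than rejected, so degenerate motifs can
  themselves be reverse-complemented for minus-strand search;
* protein records reaching a complement operation fail loudly rather than
  passing through silently.

The test suite checks the table against an independently written pairing
dictionary on sampled IUPAC strings of every length 1–8, checks involution
on 10^4 random DNA strings, and cross-checks against Biostrings.

## Regions

Regions are 1-based inclusive `start:end` pairs; a negative endpoint counts
from the sequence end (`-1` = last base), so `1:-1` is the whole sequence
and `-12:-1` the last 12 bases. Negative values map as `length + value + 1`.
Out-of-range endpoints are *clamped* into `[1, length]` rather than
rejected — the `1:-1` idiom implies forgiving semantics — but a region that
is inverted after resolution (`5:2`) is an error, as is a zero coordinate.
The resolver is tested against a brute-force oracle that materialises the
index list and slices it, over every endpoint pair within ±(L+5) for a grid
of lengths up to 50.

Feature extraction follows the standard conventions the formats imply: BED
is 0-based half-open, GTF 1-based inclusive. Flanks apply in strand
orientation (upstream of a minus-strand feature extends to higher plus
coordinates), intervals clip at `[1, chrom length]`, and minus-strand
output is reverse-complemented. With `only_flank` and both flanks
requested, each non-empty flank is emitted as its own record, upstream
first — the combined case is not specified by any convention, and separate
records lose no information. Output headers are `chrom_start-end` plus the
feature name (`gene_id` for GTF) when present.

## Motif search

A degenerate motif compiles to a plain regular expression by replacing each
IUPAC code with its base class — `TTSAA` becomes `TT[CG]AA`. Overlapping
occurrences are reported by default: restriction-site scanning is the
canonical use and plain regex scanning would silently swallow overlaps, so
the scanner uses a zero-width lookahead with a capture to enumerate every
start. Minus-strand hits are found by scanning the reverse-complemented
motif against the plus strand and are reported in plus-strand coordinates.
`grep` by ID (and by full header) is exact string equality, not substring —
least surprise for ID lists; regex matching is available explicitly.

## Set operations and seeded randomness

Dedup-by-content keys records by the MD5 digest of the sequence
(upper-folded only under `ignore_case`; gaps are not stripped — digest
canonicalisation is a dialect choice and is documented as such), so
comparing two long sequences never requires holding both: digests are 32
bytes regardless of sequence length. First occurrence wins, in `rmdup` and
for within-file duplicates in `common`.

`sample` draws without replacement via reservoir sampling (Algorithm R)
over record indices; `shuffle` draws a Fisher–Yates permutation
(`sample.int`) of the index list. Both take an integer seed, default 11 —
a fixed, documented constant, so results are reproducible *by default* and
two runs with the same data, mode and seed are byte-identical on any
platform. Because both samplers operate on indices, the in-memory and
two-pass modes of the same operation agree exactly for the same seed.
Proportion-mode sampling keeps each record independently with probability
p in a single pass, so its kept count is Binomial(n, p), not exact.

Sorts are stable throughout, with radix (byte-order) string comparison for
platform independence; natural order pads digit runs to fixed width so
`s2` sorts before `s10`. `split` offers the four partition modes (by ID,
by size, by part count with sizes differing by at most one, by the
subsequence at a region, upper-folded); file names are sanitised to
`[A-Za-z0-9._-]`.

## FASTA index and two-pass mode

`build_faidx()` writes `<input>.seqkit.fai`, five tab-separated columns in
samtools `.fai` order (NAME, LENGTH, OFFSET, LINEBASES, LINEWIDTH), keyed
by the *full header* by default so the original header can be restored; the
first-token variant is byte-compatible with samtools on description-free
headers, and the test suite asserts exactly that against `samtools faidx`.
Ragged records (internal sequence lines of unequal length) and duplicate
keys are build-time errors — random access over either would be wrong or
ambiguous. A stale sidecar (older than its FASTA) is rebuilt. gzip FASTA is
decompressed to a temporary file for indexing, since gzip streams are not
seekable; the entries are identical to the uncompressed twin's.

`fetch` reads only the byte range an entry implies, computing the byte of
base b as `offset + (b-1) %/% line_bases * line_bytes + (b-1) %% line_bases`.
Two-pass `sort`/`shuffle`/`subseq`/`split` collect keys and lengths on pass
one and fetch records in output order on pass two; the random access itself
touches one record's bytes at a time, though the returned tibble — like
every tibble — holds all its rows. Two-pass mode is FASTA-only (FASTQ input
is an explicit unsupported-mode error) and its output is record-for-record
identical to the in-memory mode, which the suite asserts on 200–500-record
fixtures.

## Command-line surface

One entry point, nineteen subcommands, shared global flags (`--seq-type`,
`--threads/-j`, `--line-width/-w`, `--id-regexp`, `--out-file/-o`,
`--quiet`). Every subcommand reads `-` and gzip and writes to `-o` (gzip
iff the name ends `.gz`), so pipelines like `seq -r -p | grep | fx2tab`
compose without temporary files. Diagnostics go to standard error only;
exit codes are 0 (success), 1 (data error: malformed records, failed
validation), 2 (usage error) — a scheme chosen here, as is conventional for
Unix filters. `--threads` defaults to 2 and is a contract, not a promise of
parallel execution: processing is sequential in this implementation, so
results are trivially independent of the worker count, and the suite
byte-compares outputs at `-j 1` and `-j 4` to pin the contract down.

## The fixture generator

`sim_fastx()` is the only source of test data: records drawn uniformly over
the alphabet, lengths fixed or uniform on a range, FASTQ qualities uniform
over the printable Phred+33 range `!`–`I` — a format toolkit needs
structural realism (multi-line wrapping, gzip, duplicates, planted motifs,
header descriptions), not an error model, so no read-simulator realism is
attempted. The generator can plant content-duplicates (fresh IDs, so
dedup-by-content has exact ground truth) and motif occurrences at known
positions (motifs are planted before duplication so duplicate pairs stay
identical); the manifest reports both, and tests verify the manifest by
re-parsing the fixture. Output is a pure function of parameters and seed:
same call, byte-identical file.

What passing these tests shows about real data: correct handling of the
format dialects the generator emulates. What it cannot show: behaviour on
pathological real-world inputs (mixed line endings within one file,
unusual header encodings, quality alphabets outside Phred+33), which the
parser handles by rule rather than by tested example.

## Problem sizes and test budget

The suite runs on one CPU in a few minutes: property loops use 200–500
records for equivalence checks, 10^4 records/strings where a distributional
bound needs headroom (binomial sampling counts, revcomp involution), 2,000
seeded trials for sampling uniformity, and a ~24k-case grid for region
resolution. These sizes are chosen so every property is exercised at a
scale where failure modes (off-by-one at wrap boundaries, last-record
truncation, tie-breaking) actually occur, while the whole suite stays
desk-scale.

## Known limitations

* No FASTQ quality trimming or re-encoding, and no BAM/SAM input — both are
  deliberately out of scope; dedicated tools do them better and their
  output pipes straight in.
* No translation to protein; complementation and transcription are the only
  alphabet transforms.
* Standard-input (`-`) processing buffers the whole stream (see above).
* `rename` guarantees unique output IDs for inputs whose IDs do not already
  use its own `_k` suffix scheme; adversarial inputs mixing `a` and `a_2`
  can still collide.
* Fuzzy (mismatch-tolerant) motif search is not provided; motifs are exact
  up to IUPAC degeneracy.
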