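# Deterministic synthetic FASTA/FASTQ generation.
#
# Every test input is generated here, as a pure function of its parameters
# and seed: the same call produces byte-identical output anywhere. The
# generator can plant ground truth — duplicate records and motif occurrences
# at known positions — which the manifest reports for tests to verify
# against.

#' Generate synthetic sequence records
#'
#' Records are drawn uniformly over the alphabet; FASTQ qualities are drawn
#' uniformly from the printable Phred+33 range (`!` to `I`). A fraction of
#' records can be planted as content-duplicates of earlier records (with
#' fresh IDs), and a motif can be planted at a random position in a subset of
#' records; both are reported in the `manifest` attribute.
#'
#' @param n number of records.
#' @param len_min,len_max record length range (uniform; equal for fixed
#'   length). Default 100.
#' @param alphabet `"dna"`, `"rna"` or `"protein"`.
#' @param format `"fasta"` or `"fastq"`.
#' @param dup_fraction fraction of the `n` records that are duplicates of
#'   other records (content only; IDs stay unique).
#' @param motif optional motif to plant (literal letters).
#' @param motif_records how many records receive one planted motif.
#' @param prefix ID prefix.
#' @param seed integer seed (default [fastx_default_seed()]).
#' @return a record tibble with attribute `manifest`: a list with `lengths`,
#'   `dup_of` (named character: duplicate ID -> original ID) and
#'   `motif_positions` (tibble id/start/end).
#' @examples
#' x <- sim_fastx(5, len_min = 20, len_max = 30, seed = 7)
#' attr(x, "manifest")$lengths
#' @export
sim_fastx <- function(n, len_min = 100L, len_max = 100L,
                      alphabet = c("dna", "rna", "protein"),
                      format = c("fasta", "fastq"), dup_fraction = 0,
                      motif = NULL, motif_records = 0L, prefix = "seq",
                      seed = fastx_default_seed()) {
  alphabet <- match.arg(alphabet)
  format <- match.arg(format)
  letters_pool <- switch(alphabet,
    dna = c("A", "C", "G", "T"),
    rna = c("A", "C", "G", "U"),
    protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  )
  withr::with_seed(as.integer(seed), {
    n_dup <- floor(dup_fraction * n)
    n_base <- n - n_dup
    lens <- if (len_min == len_max) rep(as.integer(len_min), n_base) else {
      sample(seq.int(len_min, len_max), n_base, replace = TRUE)
    }
    seqs <- vapply(lens, function(L) {
      paste(sample(letters_pool, L, replace = TRUE), collapse = "")
    }, character(1L))
    ids <- sprintf("%s_%04d", prefix, seq_len(n_base))
    # plant motifs before duplicating so duplicate pairs stay identical
    motif_pos <- tibble::tibble(id = character(), start = integer(), end = integer())
    if (!is.null(motif) && motif_records > 0L) {
      mlen <- nchar(motif)
      eligible <- which(nchar(seqs) >= mlen)
      chosen <- utils::head(eligible, motif_records)
      for (i in chosen) {
        st <- sample.int(nchar(seqs[[i]]) - mlen + 1L, 1L)
        substr(seqs[[i]], st, st + mlen - 1L) <- motif
        motif_pos <- dplyr::bind_rows(motif_pos, tibble::tibble(
          id = ids[[i]], start = st, end = st + mlen - 1L
        ))
      }
    }
    dup_of <- character(0)
    if (n_dup > 0L) {
      src <- sample.int(n_base, n_dup, replace = FALSE)
      dup_ids <- sprintf("%s_dup_%04d", prefix, seq_len(n_dup))
      dup_of <- stats::setNames(ids[src], dup_ids)
      ids <- c(ids, dup_ids)
      seqs <- c(seqs, seqs[src])
    }
    qual <- if (format == "fastq") {
      vapply(nchar(seqs), function(L) {
        paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1L]], L, replace = TRUE),
          collapse = ""
        )
      }, character(1L))
    } else {
      NA_character_
    }
    out <- fastx_tbl(id = ids, header = ids, seq = seqs, qual = qual)
    attr(out, "manifest") <- list(
      lengths = stats::setNames(nchar(seqs), ids),
      dup_of = dup_of,
      motif_positions = motif_pos
    )
    out
  })
}

#' Write a generated fixture to disk with a JSON manifest sidecar
#'
#' @param path output path (`.gz` for gzip; extension chooses nothing — the
#'   `format` of the records does).
#' @param ... passed to [sim_fastx()].
#' @param line_width FASTA wrap width (0 = no wrap).
#' @return the record tibble, invisibly; the manifest is written to
#'   `<path>.manifest.json`.
#' @export
write_fixture <- function(path, ..., line_width = 60L) {
  x <- sim_fastx(...)
  write_fastx(x, path, line_width = line_width)
  manifest <- attr(x, "manifest")
  manifest$motif_positions <- as.data.frame(manifest$motif_positions)
  manifest$n_records <- nrow(x)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(x)
}
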