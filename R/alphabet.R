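# Nucleotide alphabets and the byte-indexed complement lookup table.
#
# The reverse complement avoids a hash lookup per base: a fixed array of 256
# byte slots is indexed directly by the ASCII code of each letter. Unmapped
# slots hold the null byte and any sequence byte landing on one raises an
# error, so invalid letters can never silently pass through.

iupac_pairs <- function(alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  # canonical + the eleven IUPAC degenerate codes; gaps map to themselves
  p <- c(
    A = if (alphabet == "dna") "T" else "U",
    C = "G", G = "C",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", V = "B", D = "H", H = "D", N = "N",
    "-" = "-", "." = "."
  )
  if (alphabet == "dna") p["T"] <- "A" else p["U"] <- "A"
  p
}

nucleic_letters <- function(alphabet = c("dna", "rna"), allow_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  core <- c(if (alphabet == "dna") "T" else "U", "A", "C", "G",
            "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  letters <- c(core, tolower(core))
  if (allow_gaps) letters <- c(letters, "-", ".")
  letters
}

#' Build the 256-slot complement lookup table
#'
#' A raw vector of exactly 256 bytes indexed by ASCII code: the slot for each
#' alphabet letter (both cases, canonical and degenerate codes, gaps) holds
#' its complement; every other slot holds the null byte `00`.
#'
#' @param alphabet `"dna"` or `"rna"` (protein has no complement and is
#'   rejected).
#' @return a raw vector of length 256.
#' @examples
#' tbl <- complement_table("dna")
#' rawToChar(tbl[utf8ToInt("A") + 1L])  # "T"
#' @export
complement_table <- function(alphabet = c("dna", "rna")) {
  if (identical(alphabet, "protein")) {
    stop_data("complement is undefined for protein sequences",
      class = "fastx_alphabet_error"
    )
  }
  alphabet <- match.arg(alphabet)
  pairs <- iupac_pairs(alphabet)
  tbl <- raw(256L)
  for (b in names(pairs)) {
    comp <- pairs[[b]]
    tbl[utf8ToInt(b) + 1L] <- as.raw(utf8ToInt(comp))
    if (b %in% LETTERS) {
      tbl[utf8ToInt(tolower(b)) + 1L] <- as.raw(utf8ToInt(tolower(comp)))
    }
  }
  tbl
}

#' Reverse complement
#'
#' Each byte of the reversed sequence is mapped through the 256-slot lookup
#' table; case is preserved (lowercase complements stay lowercase). A byte
#' whose slot holds the null marker raises an invalid-letter error naming the
#' byte and its (1-based) position in the input.
#'
#' @param seq character vector of nucleotide sequences.
#' @param alphabet `"dna"` (default) or `"rna"`.
#' @param table optional prebuilt table from [complement_table()].
#' @return character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("AAAACC")  # "GGTTTT"
#' @export
reverse_complement <- function(seq, alphabet = "dna", table = NULL) {
  if (is.null(table)) table <- complement_table(alphabet)
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    bytes <- charToRaw(s)
    mapped <- table[as.integer(bytes) + 1L]
    bad <- which(mapped == as.raw(0L))
    if (length(bad)) {
      stop_data(
        sprintf("invalid letter '%s' at position %d", rawToChar(bytes[bad[[1L]]]), bad[[1L]]),
        class = "fastx_letter_error"
      )
    }
    rawToChar(rev(mapped))
  }, character(1L), USE.NAMES = FALSE)
}

#' Complement (without reversing)
#' @inheritParams reverse_complement
#' @return character vector of complemented sequences.
#' @export
complement <- function(seq, alphabet = "dna", table = NULL) {
  rc <- reverse_complement(seq, alphabet, table)
  vapply(rc, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1L), USE.NAMES = FALSE
  )
}

#' Guess the sequence type from the first record
#'
#' Inspects the leading `min(10000, length)` letters of the first sequence,
#' case-folded: all letters in the nucleic code set with no `U` is DNA; with
#' `U` and no `T` is RNA; anything else is protein.
#'
#' @param x a record tibble or a character vector of sequences (the first
#'   element is inspected).
#' @return `"dna"`, `"rna"` or `"protein"`.
#' @examples
#' guess_alphabet("ACGUACGU")  # "rna"
#' @export
guess_alphabet <- function(x) {
  seq <- if (is.data.frame(x)) x$seq else x
  if (length(seq) == 0L) return("dna")
  lead <- toupper(substr(seq[[1L]], 1L, 10000L))
  chars <- unique(strsplit(lead, "", fixed = TRUE)[[1L]])
  nuc <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
           "B", "D", "H", "V", "N", "-", ".")
  if (!all(chars %in% nuc)) return("protein")
  if ("U" %in% chars) {
    if ("T" %in% chars) return("protein")
    return("rna")
  }
  "dna"
}

#' Validate sequence letters against an alphabet
#'
#' Violations are data, not exceptions: the result is a tibble of offending
#' positions (zero rows means every record is valid). The command-line `seq
#' --validate` turns a non-empty result into exit code 1.
#'
#' @param x a record tibble.
#' @param alphabet `"auto"` (detect from first record), `"dna"`, `"rna"` or
#'   `"protein"`.
#' @param allow_gaps admit `-` and `.` as valid letters.
#' @return a tibble with columns `id`, `record` (row index), `position`
#'   (1-based), `letter`.
#' @export
fastx_validate <- function(x, alphabet = "auto", allow_gaps = FALSE) {
  check_fastx(x)
  if (alphabet == "auto") alphabet <- guess_alphabet(x)
  if (alphabet == "protein") {
    valid <- c(LETTERS, letters, "*", if (allow_gaps) c("-", "."))
  } else {
    valid <- nucleic_letters(alphabet, allow_gaps = allow_gaps)
  }
  out <- list()
  for (i in seq_len(nrow(x))) {
    chars <- strsplit(x$seq[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% valid))
    if (length(bad)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = x$id[[i]], record = i, position = bad, letter = chars[bad]
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(id = character(), record = integer(), position = integer(),
                   letter = character())
  }
}

#' Transcribe between DNA and RNA
#'
#' `dna2rna` replaces `T`/`t` with `U`/`u`; `rna2dna` is the inverse. All
#' other letters pass through unchanged.
#'
#' @param seq character vector of sequences.
#' @param direction `"dna2rna"` or `"rna2dna"`.
#' @return character vector.
#' @export
transcribe <- function(seq, direction = c("dna2rna", "rna2dna")) {
  direction <- match.arg(direction)
  if (direction == "dna2rna") chartr("Tt", "Uu", seq) else chartr("Uu", "Tt", seq)
}

#' Remove gaps and fold case
#'
#' @param seq character vector of sequences.
#' @param remove_gaps delete `-` and `.` characters.
#' @param case `"none"`, `"upper"` or `"lower"`.
#' @return character vector.
#' @export
seq_clean <- function(seq, remove_gaps = FALSE, case = c("none", "upper", "lower")) {
  case <- match.arg(case)
  if (remove_gaps) seq <- gsub("[-.]", "", seq)
  switch(case, none = seq, upper = toupper(seq), lower = tolower(seq))
}

#' Transform the sequences of a record tibble
#'
#' The engine behind the `seq` subcommand: validation aside, applies reverse,
#' complement, transcription and cleaning in a fixed order (clean, transcribe,
#' complement, reverse).
#'
#' @param x a record tibble.
#' @param reverse reverse each sequence (qualities are reversed alongside).
#' @param complement complement each sequence (nucleic alphabets only).
#' @param transcribe `NULL`, `"dna2rna"` or `"rna2dna"`.
#' @param remove_gaps drop `-`/`.` characters (FASTA only; a FASTQ sequence
#'   edit that changes length would desynchronise the quality string).
#' @param case `"none"`, `"upper"` or `"lower"`.
#' @param alphabet `"auto"`, `"dna"`, `"rna"` or `"protein"`.
#' @return the transformed record tibble.
#' @export
fastx_seq <- function(x, reverse = FALSE, complement = FALSE, transcribe = NULL,
                      remove_gaps = FALSE, case = "none", alphabet = "auto") {
  check_fastx(x)
  if (alphabet == "auto") alphabet <- guess_alphabet(x)
  if (remove_gaps && any(is_fastq(x))) {
    lens_before <- nchar(x$seq)
    cleaned <- seq_clean(x$seq, remove_gaps = TRUE)
    if (any(nchar(cleaned) != lens_before & is_fastq(x))) {
      stop_data("cannot remove gaps from FASTQ records: quality would desynchronise",
        class = "fastx_edit_error"
      )
    }
  }
  x$seq <- seq_clean(x$seq, remove_gaps = remove_gaps, case = case)
  if (!is.null(transcribe)) x$seq <- fastxkit::transcribe(x$seq, transcribe)
  if (complement && reverse) {
    x$seq <- reverse_complement(x$seq, alphabet)
    x$qual <- ifelse(is.na(x$qual), x$qual, str_reverse(x$qual))
  } else if (complement) {
    x$seq <- fastxkit::complement(x$seq, alphabet)
  } else if (reverse) {
    x$seq <- str_reverse(x$seq)
    x$qual <- ifelse(is.na(x$qual), x$qual, str_reverse(x$qual))
  }
  as_fastx_tbl(x)
}

str_reverse <- function(s) {
  vapply(s, function(z) {
    paste(rev(strsplit(z, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
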