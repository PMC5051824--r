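# Motif search with IUPAC degenerate codes.
#
# A degenerate motif compiles to a plain regular expression by replacing each
# IUPAC code with its bracketed base class (S -> [CG], N -> [ACGT], ...), so
# TTSAA — the AgsI digestion site — becomes TT[CG]AA. Overlapping occurrences
# are reported by default (restriction sites overlap); minus-strand hits are
# found by scanning the reverse-complemented motif against the plus strand
# and are reported in plus-strand coordinates.

iupac_regex_classes <- function() {
  c(
    A = "A", C = "C", G = "G", T = "T", U = "U",
    R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
    M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
    N = "[ACGT]"
  )
}

#' Compile a degenerate IUPAC motif into a regular expression
#'
#' @param motif motif text over the IUPAC nucleotide alphabet
#'   (case-insensitive).
#' @return the compiled regular-expression string.
#' @examples
#' degenerate_to_regex("TTSAA")  # "TT[CG]AA"
#' @export
degenerate_to_regex <- function(motif) {
  classes <- iupac_regex_classes()
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% names(classes)))
  if (length(bad)) {
    stop_data(
      sprintf("invalid letter '%s' in degenerate motif '%s'", chars[[bad[[1L]]]], motif),
      class = "fastx_motif_error"
    )
  }
  paste0(classes[chars], collapse = "")
}

#' Filter records by ID, header or sequence pattern
#'
#' A record is emitted iff any pattern matches its target field, XOR `invert`.
#' `by = "id"` compares the extracted ID for exact equality (or by regular
#' expression with `use_regex`); `by = "name"` does the same against the full
#' header; `by = "seq"` searches for the pattern anywhere in the sequence.
#' Input order is preserved.
#'
#' @param x a record tibble.
#' @param pattern character vector of patterns (IDs, headers, regexes or
#'   motifs). Exactly one of `pattern`/`id_file` must be given.
#' @param id_file path to a file of IDs, one per line.
#' @param by target field: `"id"`, `"name"` or `"seq"`.
#' @param use_regex treat patterns as regular expressions.
#' @param degenerate compile patterns as IUPAC degenerate motifs (implies
#'   `by = "seq"`).
#' @param invert emit the non-matching records instead.
#' @param ignore_case case-insensitive matching (default on for degenerate
#'   motifs).
#' @return the matching subset of `x`, in input order.
#' @examples
#' x <- fastx_tbl(id = c("s1", "s2", "s3"), seq = c("AAA", "CCC", "GGG"))
#' fastx_grep(x, pattern = c("s2", "s3"))
#' @export
fastx_grep <- function(x, pattern = NULL, id_file = NULL,
                       by = c("id", "name", "seq"), use_regex = FALSE,
                       degenerate = FALSE, invert = FALSE,
                       ignore_case = degenerate) {
  check_fastx(x)
  by <- match.arg(by)
  if (degenerate) by <- "seq"
  if (is.null(pattern) && is.null(id_file)) {
    stop_usage("one of `pattern` or `id_file` is required")
  }
  if (!is.null(pattern) && !is.null(id_file)) {
    stop_usage("give exactly one of `pattern` or `id_file`")
  }
  if (!is.null(id_file)) {
    if (!file.exists(id_file)) {
      stop_data(sprintf("cannot read ID file: %s", id_file), class = "fastx_file_error")
    }
    pattern <- readLines(id_file, warn = FALSE)
    pattern <- trimws(sub("\r$", "", pattern))
    pattern <- pattern[nzchar(pattern)]
  }
  if (length(pattern) == 0L) stop_usage("empty pattern set")

  target <- switch(by, id = x$id, name = x$header, seq = x$seq)
  if (degenerate) {
    pattern <- vapply(pattern, degenerate_to_regex, character(1L), USE.NAMES = FALSE)
    use_regex <- TRUE
  }
  if (ignore_case) {
    target_cmp <- toupper(target)
    pattern_cmp <- if (use_regex && !degenerate) pattern else toupper(pattern)
  } else {
    target_cmp <- target
    pattern_cmp <- pattern
  }
  hit <- rep(FALSE, length(target))
  for (p in pattern_cmp) {
    hit <- hit | if (by == "seq") {
      if (use_regex) grepl(p, target_cmp, perl = TRUE, ignore.case = ignore_case && !degenerate)
      else grepl(p, target_cmp, fixed = TRUE)
    } else if (use_regex) {
      grepl(p, target_cmp, perl = TRUE, ignore.case = ignore_case)
    } else {
      target_cmp == p
    }
  }
  keep <- xor(hit, invert)
  as_fastx_tbl(x[keep, , drop = FALSE])
}

# all (possibly overlapping) match positions of a compiled regex
regex_hits <- function(seq, regex, allow_overlap = TRUE) {
  if (allow_overlap) {
    # zero-width lookahead captures the match so overlaps are not swallowed
    m <- gregexpr(sprintf("(?=(%s))", regex), seq, perl = TRUE)[[1L]]
    if (m[[1L]] == -1L) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1L]
  } else {
    m <- gregexpr(regex, seq, perl = TRUE)[[1L]]
    if (m[[1L]] == -1L) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
  }
  keep <- lens > 0L
  cbind(start = starts[keep], end = starts[keep] + lens[keep] - 1L)
}

#' Locate every motif occurrence with coordinates and strand
#'
#' Every occurrence of each motif on the plus strand of each record is
#' reported with 1-based inclusive coordinates. With `both_strands` the
#' reverse-complemented motif is also scanned against the plus strand and
#' hits are reported with strand `-` (coordinates stay on the plus strand).
#'
#' @param x a record tibble.
#' @param motifs character vector of motifs (non-empty).
#' @param degenerate compile motifs as IUPAC degenerate patterns.
#' @param both_strands also search the minus strand.
#' @param allow_overlap report overlapping occurrences (default).
#' @param ignore_case case-insensitive scan (default on for degenerate
#'   motifs).
#' @return a tibble of hits: `seq_id`, `pattern` (raw motif), `strand`,
#'   `start`, `end`, `matched` (plus-strand letters), sorted by record order,
#'   start, strand.
#' @examples
#' fastx_locate(fastx_tbl(id = "s", seq = "ACGACG"), "ACG")
#' @export
fastx_locate <- function(x, motifs, degenerate = FALSE, both_strands = FALSE,
                         allow_overlap = TRUE, ignore_case = degenerate) {
  check_fastx(x)
  if (length(motifs) == 0L) stop_usage("`motifs` must be non-empty")
  compiled <- if (degenerate) {
    vapply(motifs, degenerate_to_regex, character(1L), USE.NAMES = FALSE)
  } else {
    motifs
  }
  rc_compiled <- if (both_strands) {
    rc_raw <- reverse_complement(toupper(motifs))
    if (degenerate) vapply(rc_raw, degenerate_to_regex, character(1L), USE.NAMES = FALSE) else rc_raw
  }
  rows <- list()
  for (i in seq_len(nrow(x))) {
    s <- if (ignore_case) toupper(x$seq[[i]]) else x$seq[[i]]
    rec_rows <- list()
    for (j in seq_along(motifs)) {
      plus <- regex_hits(s, compiled[[j]], allow_overlap)
      hits <- if (!is.null(plus)) {
        cbind(plus, strand = rep(1L, nrow(plus)))
      }
      if (both_strands) {
        minus <- regex_hits(s, rc_compiled[[j]], allow_overlap)
        if (!is.null(minus)) {
          minus <- cbind(minus, strand = rep(2L, nrow(minus)))
          hits <- rbind(hits, minus)
        }
      }
      if (is.null(hits)) next
      rec_rows[[length(rec_rows) + 1L]] <- tibble::tibble(
        seq_id = x$id[[i]],
        pattern = motifs[[j]],
        strand = c("+", "-")[hits[, "strand"]],
        start = as.integer(hits[, "start"]),
        end = as.integer(hits[, "end"]),
        matched = substr(rep(x$seq[[i]], nrow(hits)), hits[, "start"], hits[, "end"])
      )
    }
    if (length(rec_rows)) {
      rec <- dplyr::bind_rows(rec_rows)
      rows[[length(rows) + 1L]] <- rec[order(rec$start, match(rec$strand, c("+", "-"))), , drop = FALSE]
    }
  }
  if (length(rows) == 0L) {
    return(structure(
      tibble::tibble(seq_id = character(), pattern = character(), strand = character(),
                     start = integer(), end = integer(), matched = character()),
      class = c("fastx_hits", class(tibble::tibble()))
    ))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fastx_hits", class(out))
  out
}
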