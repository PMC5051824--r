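# Ordering and header/sequence editing.

#' Shuffle records with a seeded Fisher-Yates permutation
#'
#' The permutation is drawn over the record indices, so the in-memory and
#' two-pass modes produce the same order for the same seed; identical input
#' and seed give identical output everywhere.
#'
#' @param x a record tibble.
#' @param seed integer seed (default [fastx_default_seed()]).
#' @return a permuted record tibble.
#' @export
fastx_shuffle <- function(x, seed = fastx_default_seed()) {
  check_fastx(x)
  perm <- shuffle_permutation(nrow(x), seed)
  as_fastx_tbl(x[perm, , drop = FALSE])
}

shuffle_permutation <- function(n, seed) {
  if (n == 0L) return(integer(0))
  withr::with_seed(as.integer(seed), sample.int(n))
}

# natural-order key: digit runs padded so lexicographic order is numeric
natural_key <- function(s) {
  vapply(s, function(z) {
    m <- gregexpr("\\d+", z)
    if (m[[1L]][[1L]] == -1L) return(z)
    runs <- regmatches(z, m)[[1L]]
    regmatches(z, m) <- list(sprintf("%020.0f", as.numeric(runs)))
    z
  }, character(1L), USE.NAMES = FALSE)
}

#' Sort records by ID, name, sequence or length
#'
#' Sorts are stable (ties keep input order) and platform-independent (C
#' locale byte order for strings). Natural order compares digit runs
#' numerically, so `s2` sorts before `s10`.
#'
#' @param x a record tibble.
#' @param by `"id"`, `"name"` (full header), `"seq"` (lexicographic) or
#'   `"length"`.
#' @param reverse sort in decreasing order.
#' @param natural natural (alphanumeric) order for string keys.
#' @return the sorted record tibble.
#' @examples
#' x <- fastx_tbl(id = c("s10", "s2"), seq = c("AA", "CC"))
#' fastx_sort(x, by = "id", natural = TRUE)
#' @export
fastx_sort <- function(x, by = c("id", "name", "seq", "length"),
                       reverse = FALSE, natural = FALSE) {
  check_fastx(x)
  by <- match.arg(by)
  key <- switch(by,
    id = x$id,
    name = x$header,
    seq = x$seq,
    length = nchar(x$seq)
  )
  if (natural && is.character(key)) key <- natural_key(key)
  ord <- order(key, method = "radix", decreasing = reverse)
  as_fastx_tbl(x[ord, , drop = FALSE])
}

#' Edit headers or sequences by regular expression
#'
#' Every non-overlapping match of `pattern` in the target field is replaced.
#' The replacement may reference capture groups as `{1}`, `{2}`, ... and the
#' 1-based record ordinal as `{nr}`.
#'
#' @param x a record tibble.
#' @param pattern a regular expression.
#' @param replacement replacement text (`{k}` for capture group k, `{nr}` for
#'   the record counter).
#' @param by `"name"` (the full header; IDs are re-extracted) or `"seq"`.
#' @return the edited record tibble.
#' @examples
#' x <- fastx_tbl(header = c("a 1", "b 2"), seq = c("AC", "GT"))
#' fastx_replace(x, "^.+$", "seq_{nr}")
#' @export
fastx_replace <- function(x, pattern, replacement, by = c("name", "seq")) {
  check_fastx(x)
  by <- match.arg(by)
  ok <- tryCatch({
    suppressWarnings(grepl(pattern, "", perl = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop_data(sprintf("invalid regular expression: %s", pattern),
      class = "fastx_pattern_error"
    )
  }
  repl_base <- gsub("\\{(\\d+)\\}", "\\\\\\1", replacement)
  n <- nrow(x)
  target <- if (by == "name") x$header else x$seq
  has_nr <- grepl("{nr}", replacement, fixed = TRUE)
  out <- if (has_nr) {
    vapply(seq_len(n), function(i) {
      gsub(pattern, gsub("{nr}", as.character(i), repl_base, fixed = TRUE),
        target[[i]], perl = TRUE
      )
    }, character(1L))
  } else {
    gsub(pattern, repl_base, target, perl = TRUE)
  }
  if (by == "name") {
    x$header <- out
    x$id <- extract_id(out)
  } else {
    changed <- nchar(out) != nchar(x$seq) & is_fastq(x)
    if (any(changed)) {
      stop_data(
        sprintf("sequence replacement changes the length of FASTQ record '%s'; quality would desynchronise",
          x$id[[which(changed)[[1L]]]]),
        class = "fastx_edit_error"
      )
    }
    x$seq <- out
  }
  as_fastx_tbl(x)
}

#' Rename duplicated IDs
#'
#' The first occurrence of an ID is untouched; the k-th duplicate (k >= 2)
#' gets `_k` appended to the ID token inside the header. Resulting IDs are
#' unique; record count and sequences are unchanged.
#'
#' @param x a record tibble.
#' @return the renamed record tibble.
#' @examples
#' x <- fastx_tbl(id = c("a", "a", "b"), seq = c("A", "C", "G"))
#' fastx_rename(x)$id  # "a" "a_2" "b"
#' @export
fastx_rename <- function(x) {
  check_fastx(x)
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(x))) {
    id <- x$id[[i]]
    k <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
    counts[[id]] <- k
    if (k > 1L) {
      new_id <- sprintf("%s_%d", id, k)
      x$header[[i]] <- annotate_header(x$header[[i]], id, sprintf("_%d", k))
      x$id[[i]] <- new_id
    }
  }
  as_fastx_tbl(x)
}
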