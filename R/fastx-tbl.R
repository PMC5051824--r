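#' The record tibble
#'
#' Every verb in fastxkit operates on a *record tibble*: a [tibble::tibble()]
#' with one row per sequence record and columns
#' \describe{
#'   \item{id}{identifier token, extracted from the header by the active ID
#'     pattern (default: first whitespace-delimited token)}
#'   \item{header}{full header line, without the leading `>`/`@` and without
#'     the newline}
#'   \item{seq}{sequence letters, free of newlines}
#'   \item{qual}{per-base quality string (same length as `seq`) for FASTQ
#'     records, `NA` for FASTA records}
#' }
#' The format of a record is implied by `qual`: a record is FASTQ iff `qual`
#' is not `NA`.
#'
#' @param id,header,seq,qual character vectors, recycled to a common length.
#'   `header` defaults to `id`; `id` defaults to the first whitespace-delimited
#'   token of `header`.
#' @return a record tibble.
#' @examples
#' fastx_tbl(header = c("s1 some gene", "s2"), seq = c("ACGT", "GGCC"))
#' @export
fastx_tbl <- function(id = NULL, header = NULL, seq = character(), qual = NA_character_) {
  if (is.null(header)) header <- if (is.null(id)) character() else id
  if (is.null(id)) id <- extract_id(header)
  out <- tibble::tibble(
    id = as.character(id),
    header = as.character(header),
    seq = as.character(seq),
    qual = as.character(qual)
  )
  class(out) <- c("fastx_tbl", class(out))
  out
}

as_fastx_tbl <- function(x) {
  if (!inherits(x, "fastx_tbl")) class(x) <- c("fastx_tbl", class(x))
  x
}

#' Default ID pattern: capture the first whitespace-delimited token.
#' @keywords internal
#' @noRd
default_id_pattern <- function() "^(\\S+)"

#' Extract record IDs from full headers
#'
#' @param header character vector of full headers.
#' @param id_pattern regular expression with one capture group; the captured
#'   text is the ID. Headers that do not match keep the full header as ID.
#' @return character vector of IDs.
#' @export
extract_id <- function(header, id_pattern = default_id_pattern()) {
  m <- regexec(id_pattern, header, perl = TRUE)
  g <- regmatches(header, m)
  vapply(seq_along(header), function(i) {
    if (length(g[[i]]) >= 2L) g[[i]][[2L]] else header[[i]]
  }, character(1L))
}

is_fastq <- function(x) !is.na(x$qual)

check_fastx <- function(x, arg = "x") {
  if (!is.data.frame(x) || !all(c("id", "header", "seq", "qual") %in% names(x))) {
    rlang::abort(
      sprintf("`%s` must be a record tibble with columns id, header, seq, qual", arg),
      class = "fastx_usage_error"
    )
  }
  invisible(x)
}

stop_data <- function(msg, class = NULL, ...) {
  rlang::abort(msg, class = c(class, "fastx_data_error"), ...)
}

stop_usage <- function(msg, ...) {
  rlang::abort(msg, class = "fastx_usage_error", ...)
}

#' Summarise a record tibble
#'
#' `glance()` on a record tibble returns the same one-row summary as
#' [fastx_stats()].
#'
#' @param x a record tibble.
#' @param ... unused.
#' @return a one-row tibble (see [fastx_stats()]).
#' @importFrom generics glance
#' @export
#' @method glance fastx_tbl
glance.fastx_tbl <- function(x, ...) fastx_stats(x)

#' @export
generics::glance
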