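#' @keywords internal
"_PACKAGE"

# ---- connections -----------------------------------------------------------

#' Open a path, gzip file or standard stream for reading/writing
#'
#' Input gzip is detected from the two magic bytes `0x1f 0x8b` (local files are
#' simply opened through [gzfile()], which performs the same detection);
#' output is gzip-compressed iff the file name ends in `.gz`. The sentinel
#' `"-"` denotes the standard stream. Standard input is buffered fully before
#' decompression because R connections cannot be rewound after sniffing the
#' magic bytes.
#'
#' @param path file path or `"-"`.
#' @param mode `"read"` or `"write"`.
#' @return a connection, open in text mode. Callers must close it (the
#'   standard streams are returned as-is and are not closed).
#' @export
fastx_connection <- function(path, mode = c("read", "write")) {
  mode <- match.arg(mode)
  if (mode == "read") {
    if (identical(path, "-")) {
      std <- file("stdin", "rb")
      chunks <- list()
      repeat {
        chunk <- readBin(std, what = "raw", n = 1048576L)
        if (length(chunk) == 0L) break
        chunks[[length(chunks) + 1L]] <- chunk
      }
      close(std)
      raw_in <- unlist(chunks, use.names = FALSE)
      if (is.null(raw_in)) raw_in <- raw(0)
      if (length(raw_in) >= 2L && raw_in[1L] == as.raw(0x1f) && raw_in[2L] == as.raw(0x8b)) {
        raw_in <- memDecompress(raw_in, type = "gzip")
      }
      con <- rawConnection(raw_in, "rb")
      return(con)
    }
    if (!file.exists(path)) {
      stop_data(sprintf("file not found: %s", path), class = "fastx_file_error")
    }
    # gzfile() transparently reads both plain and gzip-compressed files
    con <- gzfile(path, "rb")
    return(con)
  }
  if (identical(path, "-")) return(stdout())
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

close_unless_std <- function(con) {
  if (!identical(con, stdout()) && !identical(con, stderr())) close(con)
  invisible(NULL)
}

# ---- streaming reader ------------------------------------------------------

# A pull-based record reader: returns a function that yields one record
# (a list with id/header/seq/qual) per call and NULL at end of stream. At most
# one record is materialised at a time; lines are pulled from the connection
# in fixed-size blocks.
new_line_source <- function(con, block = 4096L) {
  buf <- character(0)
  i <- 0L
  n_read <- 0L
  eof <- FALSE
  pushed <- NULL
  list(
    next_line = function() {
      if (!is.null(pushed)) {
        out <- pushed
        pushed <<- NULL
        return(out)
      }
      if (i >= length(buf)) {
        if (eof) return(NULL)
        buf <<- readLines(con, n = block, warn = FALSE)
        i <<- 0L
        if (length(buf) < block) eof <<- TRUE
        if (length(buf) == 0L) return(NULL)
        # strip Windows CRLF endings
        buf <<- sub("\r$", "", buf)
      }
      i <<- i + 1L
      n_read <<- n_read + 1L
      buf[[i]]
    },
    push_back = function(line) pushed <<- line,
    line_no = function() n_read
  )
}

#' Detect the format of a FASTA/FASTQ stream
#'
#' Peeks at the first non-whitespace byte: `>` means FASTA, `@` means FASTQ.
#'
#' @param path file path (plain or gzip) or `"-"` for standard input.
#' @return `"fasta"`, `"fastq"`, or `NA` for an empty stream.
#' @examples
#' f <- tempfile(); writeLines(c(">s1", "ACGT"), f)
#' fastx_detect_format(f)
#' @export
fastx_detect_format <- function(path) {
  con <- fastx_connection(path, "read")
  on.exit(close_unless_std(con))
  src <- new_line_source(con)
  repeat {
    line <- src$next_line()
    if (is.null(line)) return(NA_character_)
    line <- trimws(line)
    if (nzchar(line)) break
  }
  first <- substr(line, 1L, 1L)
  if (first == ">") return("fasta")
  if (first == "@") return("fastq")
  stop_data(
    sprintf("malformed input: expected '>' or '@' as first byte, got '%s'", first),
    class = "fastx_malformed_error"
  )
}

fastx_record_reader <- function(con, id_pattern = default_id_pattern()) {
  src <- new_line_source(con)
  fmt <- NULL

  read_fasta_record <- function(first_header) {
    header <- sub("^>", "", first_header)
    seq_parts <- character(0)
    repeat {
      line <- src$next_line()
      if (is.null(line)) break
      if (startsWith(line, ">")) {
        src$push_back(line)
        break
      }
      if (nzchar(line)) seq_parts <- c(seq_parts, line)
    }
    list(header = header, seq = paste0(seq_parts, collapse = ""), qual = NA_character_)
  }

  read_fastq_record <- function(first_header) {
    header <- sub("^@", "", first_header)
    seq_parts <- character(0)
    repeat {
      line <- src$next_line()
      if (is.null(line)) {
        stop_data(
          sprintf("truncated FASTQ record '%s' near line %d", header, src$line_no()),
          class = "fastx_malformed_error"
        )
      }
      if (startsWith(line, "+")) break
      if (nzchar(line)) seq_parts <- c(seq_parts, line)
    }
    seq <- paste0(seq_parts, collapse = "")
    qual_parts <- character(0)
    qlen <- 0L
    slen <- nchar(seq)
    while (qlen < slen) {
      line <- src$next_line()
      if (is.null(line)) {
        stop_data(
          sprintf("truncated FASTQ record '%s' near line %d", header, src$line_no()),
          class = "fastx_malformed_error"
        )
      }
      if (!nzchar(line)) next
      qual_parts <- c(qual_parts, line)
      qlen <- qlen + nchar(line)
    }
    if (qlen != slen) {
      stop_data(
        sprintf(
          "malformed FASTQ record '%s' near line %d: quality length %d != sequence length %d",
          header, src$line_no(), qlen, slen
        ),
        class = "fastx_malformed_error"
      )
    }
    list(header = header, seq = seq, qual = paste0(qual_parts, collapse = ""))
  }

  function() {
    repeat {
      line <- src$next_line()
      if (is.null(line)) return(NULL)
      if (nzchar(trimws(line))) break
    }
    first <- substr(line, 1L, 1L)
    if (is.null(fmt)) {
      fmt <<- switch(first,
        ">" = "fasta",
        "@" = "fastq",
        stop_data(
          sprintf("malformed input: expected '>' or '@' as first byte, got '%s'", first),
          class = "fastx_malformed_error"
        )
      )
    }
    rec <- if (fmt == "fasta") read_fasta_record(line) else read_fastq_record(line)
    rec$id <- extract_id(rec$header, id_pattern)
    rec
  }
}

# Apply `fn(record)` to each record of a stream in order; at most one record
# is buffered at any time. Stops early if fn returns FALSE.
fastx_stream <- function(path, fn, id_pattern = default_id_pattern()) {
  con <- fastx_connection(path, "read")
  on.exit(close_unless_std(con))
  nxt <- fastx_record_reader(con, id_pattern)
  repeat {
    rec <- nxt()
    if (is.null(rec)) break
    keep_going <- fn(rec)
    if (identical(keep_going, FALSE)) break
  }
  invisible(NULL)
}

#' Read a FASTA/FASTQ file into a record tibble
#'
#' Accepts plain or gzip-compressed files (multi-line records in either
#' format) and `"-"` for standard input; the format is autodetected from the
#' first record delimiter.
#'
#' @param path file path or `"-"`.
#' @param id_pattern regular expression with one capture group used to extract
#'   the ID from the full header. Default: first whitespace-delimited token.
#' @return a record tibble (see [fastx_tbl()]).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "ACGT", "AC"), f)
#' read_fastx(f)
#' @export
read_fastx <- function(path, id_pattern = default_id_pattern()) {
  recs <- vector("list", 64L)
  n <- 0L
  fastx_stream(path, function(rec) {
    n <<- n + 1L
    if (n > length(recs)) recs[2L * n] <<- list(NULL)
    recs[[n]] <<- rec
    TRUE
  }, id_pattern = id_pattern)
  recs <- recs[seq_len(n)]
  fastx_tbl(
    id = vapply(recs, `[[`, character(1L), "id"),
    header = vapply(recs, `[[`, character(1L), "header"),
    seq = vapply(recs, `[[`, character(1L), "seq"),
    qual = vapply(recs, `[[`, character(1L), "qual")
  )
}

# ---- writer ----------------------------------------------------------------

wrap_seq <- function(seq, width) {
  if (width <= 0L) return(as.list(seq))
  lapply(seq, function(s) {
    len <- nchar(s)
    if (len == 0L) return("")
    starts <- seq.int(1L, len, by = width)
    substring(s, starts, pmin(starts + width - 1L, len))
  })
}

#' Write a record tibble as FASTA or FASTQ
#'
#' FASTA sequences are wrapped at `line_width` (0 disables wrapping); FASTQ is
#' always written as four lines per record with a bare `+` separator.
#' Output is gzip-compressed iff `path` ends in `.gz`; `"-"` writes to
#' standard output.
#'
#' @param x a record tibble.
#' @param path output path, `"-"` for standard output.
#' @param format `"auto"` (FASTQ iff every record has a quality), `"fasta"`,
#'   or `"fastq"`.
#' @param line_width FASTA wrap width in bases (default 60; 0 = no wrap).
#' @return `x`, invisibly.
#' @export
write_fastx <- function(x, path = "-", format = c("auto", "fasta", "fastq"),
                        line_width = 60L) {
  check_fastx(x)
  format <- match.arg(format)
  if (line_width < 0L) stop_usage("`line_width` must be >= 0")
  if (format == "auto") {
    format <- if (nrow(x) > 0L && all(is_fastq(x))) "fastq" else "fasta"
  }
  if (format == "fastq" && any(!is_fastq(x))) {
    stop_data("cannot write FASTQ: some records have no quality string (use fq2fa direction only)",
      class = "fastx_format_error"
    )
  }
  con <- fastx_connection(path, "write")
  on.exit(close_unless_std(con))
  if (format == "fasta") {
    chunks <- wrap_seq(x$seq, as.integer(line_width))
    lines <- unlist(
      lapply(seq_len(nrow(x)), function(i) c(paste0(">", x$header[[i]]), chunks[[i]])),
      use.names = FALSE
    )
  } else {
    lines <- as.vector(rbind(paste0("@", x$header), x$seq, "+", x$qual))
  }
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(x)
}

# ---- format conversion -----------------------------------------------------

#' Convert records to a tabular representation
#'
#' One row per record: header, sequence, quality (FASTQ only), and optional
#' length and GC-content columns. GC% counts `G`, `C` and the degenerate code
#' `S` (either case) and is 0 for an empty sequence.
#'
#' @param x a record tibble.
#' @param add_length add a `length` column (bases).
#' @param add_gc add a `gc` column (percent, 2 decimals).
#' @return a tibble with columns `name`, `seq`, then `qual`, `length`, `gc`
#'   as requested.
#' @examples
#' fx2tab(fastx_tbl(id = "s1", seq = "ACGC"), add_gc = TRUE)
#' @export
fx2tab <- function(x, add_length = FALSE, add_gc = FALSE) {
  check_fastx(x)
  out <- tibble::tibble(name = x$header, seq = x$seq)
  if (any(is_fastq(x))) out$qual <- x$qual
  if (add_length) out$length <- nchar(x$seq)
  if (add_gc) out$gc <- gc_percent(x$seq)
  out
}

#' GC content of sequences, in percent
#'
#' @param seq character vector of sequences.
#' @return numeric vector; `100 * (#G + #C + #S) / length`, 0 for empty
#'   sequences.
#' @export
gc_percent <- function(seq) {
  len <- nchar(seq)
  gc <- nchar(gsub("[^GCSgcs]", "", seq))
  ifelse(len == 0L, 0, round(100 * gc / pmax(len, 1L), 2L))
}

#' Convert tabular sequences back to records
#'
#' Inverse of [fx2tab()] without the optional columns: two columns give FASTA
#' (header, seq), three give FASTQ (header, seq, qual).
#'
#' @param x a data frame (2 or 3 columns), or a path to a TSV file read
#'   without headers.
#' @return a record tibble.
#' @export
tab2fx <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    con <- fastx_connection(x, "read")
    on.exit(close_unless_std(con))
    lines <- readLines(con, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(fastx_tbl())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(parts)
    bad <- which(ncols < 2L | ncols > 3L)
    if (length(bad)) {
      stop_data(sprintf("malformed row %d: expected 2 or 3 tab-separated columns, got %d",
        bad[[1L]], ncols[[bad[[1L]]]]
      ), class = "fastx_malformed_error")
    }
    x <- tibble::tibble(
      name = vapply(parts, `[[`, character(1L), 1L),
      seq = vapply(parts, `[[`, character(1L), 2L),
      qual = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, character(1L))
    )
  }
  if (!is.data.frame(x) || ncol(x) < 2L) {
    stop_data("tab2fx input must have 2 (FASTA) or 3 (FASTQ) columns",
      class = "fastx_malformed_error"
    )
  }
  qual <- if (ncol(x) >= 3L) as.character(x[[3L]]) else NA_character_
  fastx_tbl(header = as.character(x[[1L]]), seq = as.character(x[[2L]]), qual = qual)
}

#' Convert FASTQ records to FASTA
#'
#' Drops the quality strings; headers and sequences are preserved byte for
#' byte. FASTA input passes through unchanged with a warning.
#'
#' @param x a record tibble.
#' @return a record tibble with `qual = NA` throughout.
#' @export
fq2fa <- function(x) {
  check_fastx(x)
  if (nrow(x) > 0L && !any(is_fastq(x))) {
    rlang::warn("fq2fa: input is already FASTA; passing through unchanged")
  }
  x$qual <- NA_character_
  as_fastx_tbl(x)
}

# ---- stat / head -----------------------------------------------------------

#' Simple statistics over a record stream or tibble
#'
#' @param x a record tibble or a file path (streamed; only running totals are
#'   kept in memory).
#' @return a one-row tibble: `num_seqs`, `sum_len`, `min_len`, `avg_len`,
#'   `max_len`. All zero for empty input.
#' @examples
#' fastx_stats(fastx_tbl(id = c("a", "b"), seq = c("ACGT", "AC")))
#' @export
fastx_stats <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    n <- 0L; total <- 0; mn <- Inf; mx <- -Inf
    fastx_stream(x, function(rec) {
      len <- nchar(rec$seq)
      n <<- n + 1L; total <<- total + len
      mn <<- min(mn, len); mx <<- max(mx, len)
      TRUE
    })
    lens <- NULL
  } else {
    check_fastx(x)
    lens <- nchar(x$seq)
    n <- length(lens); total <- sum(lens)
    mn <- if (n) min(lens) else Inf
    mx <- if (n) max(lens) else -Inf
  }
  tibble::tibble(
    num_seqs = as.integer(n),
    sum_len = as.numeric(total),
    min_len = if (n) as.numeric(mn) else 0,
    avg_len = if (n) total / n else 0,
    max_len = if (n) as.numeric(mx) else 0
  )
}

#' First n records
#'
#' @param x a record tibble or a file path. When a path is given the stream is
#'   read only as far as the n-th record.
#' @param n number of records (>= 0).
#' @return a record tibble with the first `min(n, total)` records.
#' @export
fastx_head <- function(x, n = 10L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    stop_usage("`n` must be a single non-negative number")
  }
  n <- as.integer(n)
  if (is.character(x) && length(x) == 1L) {
    recs <- vector("list", n)
    k <- 0L
    if (n > 0L) {
      fastx_stream(x, function(rec) {
        k <<- k + 1L
        recs[[k]] <<- rec
        k < n
      })
    }
    recs <- recs[seq_len(k)]
    return(fastx_tbl(
      id = vapply(recs, `[[`, character(1L), "id"),
      header = vapply(recs, `[[`, character(1L), "header"),
      seq = vapply(recs, `[[`, character(1L), "seq"),
      qual = vapply(recs, `[[`, character(1L), "qual")
    ))
  }
  check_fastx(x)
  as_fastx_tbl(x[seq_len(min(n, nrow(x))), , drop = FALSE])
}
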