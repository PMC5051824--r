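# FASTA index for random access and memory-bounded two-pass processing.
#
# The sidecar "<input>.seqkit.fai" mirrors the samtools .fai layout
# (NAME, LENGTH, OFFSET, LINEBASES, LINEWIDTH) but keys records by the FULL
# header by default, so the original header can be restored exactly; the
# first-token variant is byte-compatible with samtools for description-free
# headers. Two-pass mode collects keys and lengths on pass one and fetches
# records by byte offset on pass two, so peak buffered data is bounded by the
# longest single record.

#' Build a FASTA index
#'
#' Five tab-separated columns per record: key (full header by default, else
#' the ID token), sequence length, byte offset of the first base, bases per
#' full sequence line, and bytes per full sequence line including the
#' terminator. gzip input is transparently decompressed to a temporary file
#' first (gzip streams are not seekable); the entries are identical to those
#' of the uncompressed twin.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param full_header key records by full header (default) rather than the
#'   ID token.
#' @param out sidecar path; default `<path>.seqkit.fai`. `NA` skips writing.
#' @param id_pattern ID extraction pattern for `full_header = FALSE`.
#' @return a tibble of index entries (`key`, `length`, `offset`,
#'   `line_bases`, `line_bytes`) with attribute `fasta` giving the seekable
#'   FASTA path the offsets refer to.
#' @export
build_faidx <- function(path, full_header = TRUE, out = paste0(path, ".seqkit.fai"),
                        id_pattern = default_id_pattern()) {
  if (!file.exists(path)) {
    stop_data(sprintf("file not found: %s", path), class = "fastx_file_error")
  }
  seekable <- path
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[[1L]] == as.raw(0x1f) && magic[[2L]] == as.raw(0x8b)) {
    seekable <- tempfile(fileext = ".fa")
    gz <- gzfile(path, "rb")
    writeLines(readLines(gz, warn = FALSE), seekable, sep = "\n")
    close(gz)
  }
  bytes <- readBin(seekable, "raw", n = file.size(seekable))
  if (length(bytes) == 0L) {
    idx <- empty_faidx()
    attr(idx, "fasta") <- seekable
    if (!is.na(out)) write_faidx(idx, out)
    return(idx)
  }
  nl <- which(bytes == as.raw(0x0a))
  # tolerate a missing final newline
  if (length(nl) == 0L || nl[[length(nl)]] != length(bytes)) nl <- c(nl, length(bytes) + 1L)
  line_start <- c(1L, nl[-length(nl)] + 1L)
  line_end_excl <- nl            # exclusive of the newline itself
  line_text <- vapply(seq_along(line_start), function(i) {
    if (line_end_excl[[i]] <= line_start[[i]]) return("")
    txt <- rawToChar(bytes[line_start[[i]]:(line_end_excl[[i]] - 1L)])
    sub("\r$", "", txt)
  }, character(1L))

  entries <- list()
  keys_seen <- character(0)
  i <- 1L
  n_lines <- length(line_text)
  while (i <= n_lines) {
    if (!startsWith(line_text[[i]], ">")) {
      if (nzchar(trimws(line_text[[i]]))) {
        stop_data("malformed FASTA: sequence data before first header",
          class = "fastx_malformed_error"
        )
      }
      i <- i + 1L
      next
    }
    header <- substring(line_text[[i]], 2L)
    key <- if (full_header) header else extract_id(header, id_pattern)
    # 0-based byte offset of first base (end of file for a sequence-less record)
    offset <- if (i < n_lines) line_start[[i + 1L]] - 1L else length(bytes)
    seq_lens <- integer(0)
    line_bytes <- NA_integer_
    j <- i + 1L
    while (j <= n_lines && !startsWith(line_text[[j]], ">")) {
      len <- nchar(line_text[[j]])
      if (len > 0L) {
        seq_lens <- c(seq_lens, len)
        if (is.na(line_bytes)) {
          line_bytes <- min(nl[[j]], length(bytes) + 1L) - line_start[[j]] + 1L
        }
      }
      j <- j + 1L
    }
    if (length(seq_lens) > 1L) {
      internal <- seq_lens[-length(seq_lens)]
      if (any(internal != internal[[1L]]) || seq_lens[[length(seq_lens)]] > internal[[1L]]) {
        stop_data(
          sprintf("cannot index record '%s': internal sequence lines have unequal lengths", header),
          class = "fastx_index_error"
        )
      }
    }
    if (key %in% keys_seen) {
      stop_data(sprintf("duplicate index key '%s'", key), class = "fastx_index_error")
    }
    keys_seen <- c(keys_seen, key)
    line_bases <- if (length(seq_lens)) seq_lens[[1L]] else 0L
    if (is.na(line_bytes)) line_bytes <- line_bases + 1L
    entries[[length(entries) + 1L]] <- tibble::tibble(
      key = key,
      length = sum(seq_lens),
      offset = as.numeric(offset),
      line_bases = as.integer(line_bases),
      line_bytes = as.integer(line_bytes)
    )
    i <- j
  }
  idx <- if (length(entries)) dplyr::bind_rows(entries) else empty_faidx()
  attr(idx, "fasta") <- seekable
  if (!is.na(out)) write_faidx(idx, out)
  idx
}

empty_faidx <- function() {
  tibble::tibble(key = character(), length = integer(), offset = numeric(),
                 line_bases = integer(), line_bytes = integer())
}

write_faidx <- function(idx, path) {
  lines <- sprintf("%s\t%d\t%.0f\t%d\t%d", idx$key, idx$length, idx$offset,
                   idx$line_bases, idx$line_bytes)
  writeLines(lines, path)
  invisible(idx)
}

#' Read a FASTA index sidecar
#' @param path path to a `.seqkit.fai` (or samtools `.fai`) file.
#' @param fasta path of the FASTA file the offsets refer to (default: `path`
#'   with the index suffix removed).
#' @return an index tibble as from [build_faidx()].
#' @export
read_faidx <- function(path, fasta = sub("(\\.seqkit)?\\.fai$", "", path)) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  idx <- tibble::tibble(
    key = vapply(parts, `[[`, character(1L), 1L),
    length = as.integer(vapply(parts, `[[`, character(1L), 2L)),
    offset = as.numeric(vapply(parts, `[[`, character(1L), 3L)),
    line_bases = as.integer(vapply(parts, `[[`, character(1L), 4L)),
    line_bytes = as.integer(vapply(parts, `[[`, character(1L), 5L))
  )
  attr(idx, "fasta") <- fasta
  idx
}

# load a valid index for `path`, rebuilding when absent or older than the FASTA
faidx_for <- function(path, full_header = TRUE) {
  sidecar <- paste0(path, ".seqkit.fai")
  if (file.exists(sidecar) && file.mtime(sidecar) >= file.mtime(path)) {
    idx <- read_faidx(sidecar, fasta = path)
    magic <- readBin(path, "raw", n = 2L)
    gz <- length(magic) == 2L && magic[[1L]] == as.raw(0x1f) && magic[[2L]] == as.raw(0x8b)
    if (!gz) return(idx)
  }
  build_faidx(path, full_header = full_header)
}

#' Fetch a record (or a region of it) through the index
#'
#' Reads only the byte range implied by the index entry; the returned letters
#' are identical to what a sequential parse of the file yields for that
#' record and region.
#'
#' @param index an index tibble from [build_faidx()]/[read_faidx()].
#' @param key record key (full header or ID, per how the index was built).
#' @param region optional region string (see [resolve_region()]).
#' @param fasta FASTA path; defaults to the index's `fasta` attribute.
#' @return the sequence string.
#' @export
faidx_fetch <- function(index, key, region = NULL, fasta = attr(index, "fasta")) {
  hit <- which(index$key == key)
  if (length(hit) == 0L) {
    near <- index$key[order(utils::adist(key, index$key))]
    near <- utils::head(near, 3L)
    stop_data(
      sprintf("key not found: '%s' (nearest: %s)", key, paste(near, collapse = ", ")),
      class = "fastx_key_error"
    )
  }
  e <- index[hit[[1L]], ]
  if (e$length == 0L) return("")
  se <- if (is.null(region)) c(1L, e$length) else resolve_region(e$length, region)
  # byte position (0-based) of base b
  base_byte <- function(b) {
    b0 <- b - 1
    e$offset + (b0 %/% e$line_bases) * e$line_bytes + b0 %% e$line_bases
  }
  from <- base_byte(se[[1L]])
  to <- base_byte(se[[2L]])
  con <- file(fasta, "rb")
  on.exit(close(con))
  seek(con, where = from, origin = "start")
  chunk <- readBin(con, "raw", n = to - from + 1L)
  txt <- rawToChar(chunk)
  gsub("[\r\n]", "", txt)
}

#' Run an operation in two-pass mode over a FASTA file
#'
#' Pass one builds (or loads) the index, collecting keys and lengths; pass
#' two emits records by random access in the operation's output order. The
#' output is record-for-record identical to the same operation run in-memory.
#' Only FASTA input is supported (a FASTQ file raises an unsupported-mode
#' error).
#'
#' @param path FASTA file path (plain or gzip).
#' @param operation `"sort"`, `"shuffle"`, `"subseq"` or `"split"`.
#' @param ... passed to the operation: [fastx_sort()] arguments (`by`,
#'   `reverse`, `natural`), [fastx_shuffle()]'s `seed`, [fastx_subseq()]'s
#'   `region`, [fastx_split()] arguments.
#' @param id_pattern ID extraction pattern.
#' @return the operation's result (a record tibble, or the manifest for
#'   `"split"`).
#' @export
fastx_two_pass <- function(path, operation = c("sort", "shuffle", "subseq", "split"),
                           ..., id_pattern = default_id_pattern()) {
  operation <- match.arg(operation)
  if (identical(fastx_detect_format(path), "fastq")) {
    stop_data("two-pass mode only supports the FASTA format",
      class = "fastx_mode_error"
    )
  }
  idx <- faidx_for(path, full_header = TRUE)
  n <- nrow(idx)
  fetch_rows <- function(rows, region = NULL) {
    seqs <- vapply(rows, function(i) {
      faidx_fetch(idx, idx$key[[i]], region = region)
    }, character(1L))
    fastx_tbl(
      id = extract_id(idx$key[rows], id_pattern),
      header = idx$key[rows],
      seq = seqs
    )
  }
  args <- list(...)
  if (operation == "shuffle") {
    seed <- if (is.null(args$seed)) fastx_default_seed() else args$seed
    perm <- shuffle_permutation(n, seed)
    return(fetch_rows(perm))
  }
  if (operation == "sort") {
    by <- if (is.null(args$by)) "id" else args$by
    reverse <- isTRUE(args$reverse)
    natural <- isTRUE(args$natural)
    key <- switch(by,
      id = extract_id(idx$key, id_pattern),
      name = idx$key,
      length = idx$length,
      seq = vapply(seq_len(n), function(i) faidx_fetch(idx, idx$key[[i]]), character(1L))
    )
    if (natural && is.character(key)) key <- natural_key(key)
    ord <- order(key, method = "radix", decreasing = reverse)
    return(fetch_rows(ord))
  }
  if (operation == "subseq") {
    region <- args$region
    if (is.null(region)) stop_usage("two-pass subseq requires a `region`")
    out <- fetch_rows(seq_len(n), region = region)
    # re-annotate headers with the resolved coordinates, as in-memory subseq does
    hdr <- vapply(seq_len(n), function(i) {
      se <- resolve_region(idx$length[[i]], region)
      annotate_header(idx$key[[i]], extract_id(idx$key[[i]], id_pattern),
                      sprintf("_%d-%d", se[[1L]], se[[2L]]))
    }, character(1L))
    return(fastx_tbl(header = hdr, seq = out$seq))
  }
  # split: materialise per-group via random access
  do.call(fastx_split, c(list(x = fetch_rows(seq_len(n))), args))
}
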