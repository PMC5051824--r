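# Region arithmetic with negative coordinates.
#
# Regions are 1-based inclusive "start:end" pairs; a negative endpoint counts
# from the end of the sequence (-1 = last base), so "1:-1" is the whole
# sequence and "-12:-1" the last 12 bases. Out-of-range endpoints are clamped
# into [1, length]; a region that is inverted after resolution is an error.

#' Parse a region string
#'
#' @param region a string `"start:end"` of two non-zero integers (negative
#'   values count from the sequence end).
#' @return a list with integer `start` and `end`.
#' @examples
#' parse_region("-12:-1")
#' @export
parse_region <- function(region) {
  if (is.list(region) && all(c("start", "end") %in% names(region))) return(region)
  m <- regmatches(region, regexec("^(-?\\d+):(-?\\d+)$", region))[[1L]]
  if (length(m) != 3L) {
    stop_data(sprintf("invalid region '%s': expected 'start:end'", region),
      class = "fastx_region_error"
    )
  }
  out <- list(start = as.integer(m[[2L]]), end = as.integer(m[[3L]]))
  if (out$start == 0L || out$end == 0L) {
    stop_data(sprintf("invalid region '%s': coordinates are 1-based, 0 is not allowed", region),
      class = "fastx_region_error"
    )
  }
  out
}

#' Resolve a region against a sequence length
#'
#' Negative coordinates map as `length + value + 1`; both endpoints are then
#' clamped into `[1, length]`.
#'
#' @param length sequence length (>= 1).
#' @param region a region string or parsed region.
#' @return integer vector `c(start, end)`, 1-based inclusive,
#'   `1 <= start <= end <= length`.
#' @examples
#' resolve_region(100, "-12:-1")  # c(89, 100)
#' @export
resolve_region <- function(length, region) {
  r <- parse_region(region)
  map1 <- function(v) if (v < 0L) length + v + 1L else v
  s <- map1(r$start)
  e <- map1(r$end)
  s <- max(1L, min(s, length))
  e <- max(1L, min(e, length))
  if (s > e) {
    stop_data(
      sprintf("invalid region %d:%d on length %d: start > end after resolution", r$start, r$end, length),
      class = "fastx_region_error"
    )
  }
  c(as.integer(s), as.integer(e))
}

#' Extract a subsequence region from every record
#'
#' Sequences (and qualities, for FASTQ) are sliced to the resolved region;
#' the ID token of each header gains a `_start-end` suffix with the resolved
#' 1-based coordinates.
#'
#' @param x a record tibble.
#' @param region a region string such as `"1:20"`, `"-12:-1"`, `"1:-1"`.
#' @return a record tibble of the slices.
#' @examples
#' fastx_subseq(fastx_tbl(id = "s1", seq = "ACGTACGT"), "2:4")
#' @export
fastx_subseq <- function(x, region) {
  check_fastx(x)
  r <- parse_region(region)
  n <- nrow(x)
  seq_out <- character(n)
  qual_out <- rep(NA_character_, n)
  hdr_out <- character(n)
  for (i in seq_len(n)) {
    se <- resolve_region(nchar(x$seq[[i]]), r)
    seq_out[[i]] <- substr(x$seq[[i]], se[[1L]], se[[2L]])
    if (!is.na(x$qual[[i]])) qual_out[[i]] <- substr(x$qual[[i]], se[[1L]], se[[2L]])
    hdr_out[[i]] <- annotate_header(x$header[[i]], x$id[[i]], sprintf("_%d-%d", se[[1L]], se[[2L]]))
  }
  fastx_tbl(header = hdr_out, seq = seq_out, qual = qual_out)
}

# append a suffix to the ID token inside the full header
annotate_header <- function(header, id, suffix) {
  if (startsWith(header, id)) {
    paste0(id, suffix, substring(header, nchar(id) + 1L))
  } else {
    paste0(header, suffix)
  }
}

# ---- annotation readers ----------------------------------------------------

#' Read a BED file as a feature tibble
#'
#' 3-6 column BED; `#` comment lines tolerated. BED intervals are 0-based
#' half-open on disk and are converted to 1-based inclusive coordinates.
#'
#' @param path BED file path.
#' @return a tibble: `chrom`, `start`, `end` (1-based inclusive), `strand`
#'   (`+`, `-` or `.`), `name` (NA when absent).
#' @export
read_bed <- function(path) {
  lines <- read_annotation_lines(path)
  if (length(lines) == 0L) return(empty_features())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop_data(sprintf("malformed BED line %d: fewer than 3 columns", bad[[1L]]),
      class = "fastx_malformed_error"
    )
  }
  tibble::tibble(
    chrom = vapply(parts, `[[`, character(1L), 1L),
    start = as.integer(vapply(parts, `[[`, character(1L), 2L)) + 1L,
    end = as.integer(vapply(parts, `[[`, character(1L), 3L)),
    strand = vapply(parts, function(p) if (length(p) >= 6L) p[[6L]] else ".", character(1L)),
    name = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, character(1L))
  )
}

#' Read a GTF file as a feature tibble
#'
#' 9-column GTF, 1-based inclusive coordinates; `#` comment lines tolerated.
#' `name` is the `gene_id` attribute when present.
#'
#' @param path GTF file path.
#' @return a feature tibble (see [read_bed()]).
#' @export
read_gtf <- function(path) {
  lines <- read_annotation_lines(path)
  if (length(lines) == 0L) return(empty_features())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad)) {
    stop_data(sprintf("malformed GTF line %d: fewer than 8 columns", bad[[1L]]),
      class = "fastx_malformed_error"
    )
  }
  name <- vapply(parts, function(p) {
    if (length(p) < 9L) return(NA_character_)
    m <- regmatches(p[[9L]], regexec('gene_id[ =]+"?([^";]+)"?', p[[9L]]))[[1L]]
    if (length(m) >= 2L) m[[2L]] else NA_character_
  }, character(1L))
  tibble::tibble(
    chrom = vapply(parts, `[[`, character(1L), 1L),
    start = as.integer(vapply(parts, `[[`, character(1L), 4L)),
    end = as.integer(vapply(parts, `[[`, character(1L), 5L)),
    strand = vapply(parts, `[[`, character(1L), 7L),
    name = name
  )
}

read_annotation_lines <- function(path) {
  con <- fastx_connection(path, "read")
  on.exit(close_unless_std(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

empty_features <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), name = character())
}

#' Extract feature subsequences with optional strand-aware flanks
#'
#' For each feature the interval is extended `upstream`/`downstream` bases in
#' the feature's strand orientation (upstream of a minus-strand feature
#' extends to higher coordinates), clipped at `[1, chrom length]`.
#' Minus-strand output is reverse-complemented. With `only_flank` the feature
#' body is excluded and each non-empty flank is emitted as its own record
#' (upstream first). Features whose chrom is absent from the input are
#' skipped with a warning.
#'
#' @param x a record tibble; `id` (or full header) keys the `chrom` column.
#' @param features a feature tibble from [read_bed()]/[read_gtf()], or a path
#'   to a `.bed`/`.gtf` file.
#' @param upstream,downstream flank lengths in bases (>= 0).
#' @param only_flank emit only the flank(s), excluding the feature body.
#' @return a record tibble in feature order; headers are
#'   `chrom_start-end` (resolved plus-strand coordinates) plus the feature
#'   name when present.
#' @export
fastx_subseq_features <- function(x, features, upstream = 0L, downstream = 0L,
                                  only_flank = FALSE) {
  check_fastx(x)
  if (is.character(features) && length(features) == 1L) {
    features <- if (grepl("\\.bed(\\.gz)?$", features)) read_bed(features) else read_gtf(features)
  }
  if (upstream < 0L || downstream < 0L) stop_usage("flank lengths must be >= 0")
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(features))) {
    chrom <- features$chrom[[i]]
    # chrom keys match record IDs, or full headers as a fallback
    row <- match(chrom, x$id)
    if (is.na(row)) row <- match(chrom, x$header)
    if (is.na(row)) {
      skipped <- skipped + 1L
      next
    }
    s <- x$seq[[row]]
    L <- nchar(s)
    fs <- features$start[[i]]
    fe <- features$end[[i]]
    minus <- identical(features$strand[[i]], "-")
    up <- as.integer(upstream)
    down <- as.integer(downstream)
    # strand-aware extension: upstream of a minus-strand feature is rightwards
    ext_s <- if (minus) fs - down else fs - up
    ext_e <- if (minus) fe + up else fe + down
    intervals <- if (only_flank) {
      iv <- list()
      left <- c(ext_s, fs - 1L)   # plus-strand left flank
      right <- c(fe + 1L, ext_e)  # plus-strand right flank
      ordered <- if (minus) list(right, left) else list(left, right)
      for (f in ordered) if (f[[1L]] <= f[[2L]]) iv[[length(iv) + 1L]] <- f
      iv
    } else {
      list(c(ext_s, ext_e))
    }
    for (iv in intervals) {
      cs <- max(1L, iv[[1L]])
      ce <- min(L, iv[[2L]])
      if (cs > ce) next
      sub <- substr(s, cs, ce)
      if (minus) sub <- reverse_complement(sub)
      hdr <- sprintf("%s_%d-%d", chrom, cs, ce)
      if (!is.na(features$name[[i]])) hdr <- paste(hdr, features$name[[i]])
      out[[length(out) + 1L]] <- list(header = hdr, seq = sub)
    }
  }
  if (skipped > 0L) {
    rlang::warn(sprintf("skipped %d feature(s) whose chrom is absent from the input", skipped))
  }
  fastx_tbl(
    header = vapply(out, `[[`, character(1L), "header"),
    seq = vapply(out, `[[`, character(1L), "seq")
  )
}

#' Sliding windows over each record
#'
#' Windows start at 1, 1+step, 1+2*step, ...; a window is emitted iff it fits
#' entirely within the sequence. In circular mode windows may wrap past the
#' end. Window headers are `id:start-end` (1-based inclusive); qualities are
#' co-sliced for FASTQ.
#'
#' @param x a record tibble.
#' @param window window length in bases (>= 1).
#' @param step step in bases (>= 1).
#' @param circular wrap windows past the sequence end.
#' @return a record tibble of windows, record-major order.
#' @examples
#' fastx_sliding(fastx_tbl(id = "s", seq = "ACGTACGTAC"), window = 5, step = 5)
#' @export
fastx_sliding <- function(x, window, step, circular = FALSE) {
  check_fastx(x)
  if (window < 1L || step < 1L) stop_usage("`window` and `step` must be >= 1")
  window <- as.integer(window)
  step <- as.integer(step)
  out <- list()
  for (i in seq_len(nrow(x))) {
    s <- x$seq[[i]]
    q <- x$qual[[i]]
    L <- nchar(s)
    if (L < 1L) next
    starts <- if (circular) {
      seq.int(1L, L, by = step)
    } else if (L >= window) {
      seq.int(1L, L - window + 1L, by = step)
    } else {
      integer(0)
    }
    for (st in starts) {
      en <- st + window - 1L
      if (en <= L) {
        sub <- substr(s, st, en)
        subq <- if (is.na(q)) NA_character_ else substr(q, st, en)
      } else {
        wrap <- en - L
        sub <- paste0(substr(s, st, L), substr(s, 1L, wrap))
        subq <- if (is.na(q)) NA_character_ else paste0(substr(q, st, L), substr(q, 1L, wrap))
      }
      out[[length(out) + 1L]] <- list(
        header = sprintf("%s:%d-%d", x$id[[i]], st, en),
        seq = sub, qual = subq
      )
    }
  }
  fastx_tbl(
    header = vapply(out, `[[`, character(1L), "header"),
    seq = vapply(out, `[[`, character(1L), "seq"),
    qual = vapply(out, `[[`, character(1L), "qual")
  )
}
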