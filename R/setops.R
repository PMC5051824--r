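# Record-set manipulations: deduplication, intersection, splitting, sampling.
#
# Sequence-content keys are MD5 hex digests rather than the sequences
# themselves, so dedup-by-content never needs to hold two copies of a long
# sequence to compare them. Sampling and shuffling draw from a seeded
# generator (default seed 11) so results are reproducible by default.

#' Default seed for the seeded operations (sample, shuffle, fixtures)
#' @return integer 11.
#' @export
fastx_default_seed <- function() 11L

dedup_key <- function(x, by = c("id", "name", "seq"), ignore_case = FALSE) {
  by <- match.arg(by)
  if (by == "seq") {
    s <- if (ignore_case) toupper(x$seq) else x$seq
    return(vapply(s, function(z) as.character(cli::hash_md5(z)), character(1L),
      USE.NAMES = FALSE
    ))
  }
  key <- switch(by, id = x$id, name = x$header)
  if (ignore_case) toupper(key) else key
}

#' Remove duplicated records
#'
#' The first occurrence of each key is kept; later collisions are dropped and
#' counted. With `by = "seq"` the key is the MD5 digest of the sequence
#' (upper-folded when `ignore_case`), so only digests are retained for the
#' comparison.
#'
#' @param x a record tibble.
#' @param by duplicate key: `"id"`, `"name"` (full header) or `"seq"`
#'   (content digest).
#' @param ignore_case fold case before keying.
#' @param save_dups optional path; dropped records are written there as
#'   FASTA/FASTQ.
#' @return the deduplicated record tibble, with attributes `removed` (count)
#'   and `dups` (the dropped records).
#' @examples
#' x <- fastx_tbl(id = c("a", "b", "c"), seq = c("ACGT", "ACGT", "CCCC"))
#' fastx_rmdup(x, by = "seq")
#' @export
fastx_rmdup <- function(x, by = c("id", "name", "seq"), ignore_case = FALSE,
                        save_dups = NULL) {
  check_fastx(x)
  by <- match.arg(by)
  key <- dedup_key(x, by, ignore_case)
  dup <- duplicated(key)
  kept <- as_fastx_tbl(x[!dup, , drop = FALSE])
  dups <- as_fastx_tbl(x[dup, , drop = FALSE])
  if (!is.null(save_dups) && nrow(dups) > 0L) write_fastx(dups, save_dups)
  attr(kept, "removed") <- sum(dup)
  attr(kept, "dups") <- dups
  kept
}

#' Records of the first file common to all other files
#'
#' Emits the records of the first input whose key (per `by`; `"seq"` compares
#' MD5 digests of the content, ignoring headers) occurs in every other input.
#' First-input order is preserved; duplicate keys within a file count once.
#'
#' @param inputs a list of record tibbles and/or file paths (at least two).
#' @param by,ignore_case as in [fastx_rmdup()].
#' @return a record tibble, subset of the first input.
#' @export
fastx_common <- function(inputs, by = c("id", "name", "seq"), ignore_case = FALSE) {
  by <- match.arg(by)
  if (!is.list(inputs) || length(inputs) < 2L) {
    stop_usage("`inputs` must list at least two files or record tibbles")
  }
  tbls <- lapply(inputs, function(f) if (is.character(f)) read_fastx(f) else check_fastx(f))
  keys <- lapply(tbls, dedup_key, by = by, ignore_case = ignore_case)
  first <- tbls[[1L]]
  in_all <- Reduce(`&`, lapply(keys[-1L], function(k) keys[[1L]] %in% k))
  as_fastx_tbl(first[in_all, , drop = FALSE])
}

sanitize_filename <- function(s) gsub("[^A-Za-z0-9._-]", "_", s)

#' Split records into files
#'
#' Exactly one splitting mode must be given:
#' \describe{
#'   \item{by_id}{one file per distinct ID, records in input order}
#'   \item{by_size}{consecutive chunks of N records, the last possibly
#'     smaller}
#'   \item{by_part}{N contiguous chunks whose sizes differ by at most one}
#'   \item{by_region}{one file per distinct subsequence at the given region
#'     (grouping key = that subsequence, upper-folded)}
#' }
#' Output files partition the input: their union is the input and they are
#' pairwise disjoint.
#'
#' @param x a record tibble.
#' @param by_id logical flag.
#' @param by_size,by_part integer N (>= 1).
#' @param by_region a region string, e.g. `"1:4"`.
#' @param out_dir output directory (created if needed).
#' @param stem file-name stem (default `"part"`).
#' @param line_width FASTA wrap width.
#' @return a tibble manifest: `file`, `key`, `n`.
#' @export
fastx_split <- function(x, by_id = FALSE, by_size = NULL, by_part = NULL,
                        by_region = NULL, out_dir = ".", stem = "part",
                        line_width = 60L) {
  check_fastx(x)
  modes <- c(isTRUE(by_id), !is.null(by_size), !is.null(by_part), !is.null(by_region))
  if (sum(modes) != 1L) {
    stop_usage("give exactly one of `by_id`, `by_size`, `by_part`, `by_region`")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- nrow(x)
  groups <- if (isTRUE(by_id)) {
    split(seq_len(n), factor(x$id, levels = unique(x$id)))
  } else if (!is.null(by_size)) {
    by_size <- as.integer(by_size)
    if (is.na(by_size) || by_size < 1L) stop_usage("`by_size` must be >= 1")
    if (n == 0L) list() else split(seq_len(n), ceiling(seq_len(n) / by_size))
  } else if (!is.null(by_part)) {
    by_part <- as.integer(by_part)
    if (is.na(by_part) || by_part < 1L) stop_usage("`by_part` must be >= 1")
    if (n == 0L) list() else {
      # contiguous chunks differing in size by at most 1
      sizes <- rep(n %/% by_part, by_part) + c(rep(1L, n %% by_part), rep(0L, by_part - n %% by_part))
      sizes <- sizes[sizes > 0L]
      split(seq_len(n), rep(seq_along(sizes), sizes))
    }
  } else {
    key <- toupper(vapply(seq_len(n), function(i) {
      se <- resolve_region(nchar(x$seq[[i]]), by_region)
      substr(x$seq[[i]], se[[1L]], se[[2L]])
    }, character(1L)))
    split(seq_len(n), factor(key, levels = unique(key)))
  }
  ext <- if (n > 0L && all(is_fastq(x))) ".fq" else ".fa"
  manifest <- lapply(seq_along(groups), function(g) {
    key <- names(groups)[[g]]
    fname <- if (isTRUE(by_id) || !is.null(by_region)) {
      sprintf("%s.%s%s", stem, sanitize_filename(key), ext)
    } else {
      sprintf("%s.%03d%s", stem, g, ext)
    }
    path <- file.path(out_dir, fname)
    write_fastx(x[groups[[g]], , drop = FALSE], path, line_width = line_width)
    tibble::tibble(file = path, key = key, n = length(groups[[g]]))
  })
  if (length(manifest)) dplyr::bind_rows(manifest) else {
    tibble::tibble(file = character(), key = character(), n = integer())
  }
}

# Reservoir sampling (Algorithm R) over 1..n_total: returns k indices drawn
# uniformly without replacement, in ascending order. Used by both the
# single-pass and the two-pass samplers so the two modes agree for a seed.
reservoir_indices <- function(n_total, k, seed) {
  k <- min(k, n_total)
  if (k == 0L) return(integer(0))
  withr::with_seed(seed, {
    res <- seq_len(k)
    i <- k
    while (i < n_total) {
      i <- i + 1L
      j <- sample.int(i, 1L)
      if (j <= k) res[[j]] <- i
    }
    sort(res)
  })
}

#' Sample records by number or proportion
#'
#' Exactly one of `n` (records drawn uniformly without replacement, via
#' seeded reservoir sampling) or `p` (each record kept independently with
#' probability p, single pass) must be given. Relative input order is
#' preserved; identical inputs, mode and seed give identical output on every
#' platform.
#'
#' @param x a record tibble.
#' @param n number of records to draw (>= 0).
#' @param p keep probability in `[0, 1]`.
#' @param seed integer seed (default [fastx_default_seed()]).
#' @return the sampled record tibble.
#' @examples
#' x <- sim_fastx(20, seed = 1)
#' fastx_sample(x, n = 5, seed = 42)
#' @export
fastx_sample <- function(x, n = NULL, p = NULL, seed = fastx_default_seed()) {
  check_fastx(x)
  if (is.null(n) == is.null(p)) stop_usage("give exactly one of `n` or `p`")
  total <- nrow(x)
  if (!is.null(p)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop_usage("`p` must be a single probability in [0, 1]")
    }
    keep <- withr::with_seed(as.integer(seed), stats::runif(total) < p)
    return(as_fastx_tbl(x[keep, , drop = FALSE]))
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    stop_usage("`n` must be a single non-negative number")
  }
  idx <- reservoir_indices(total, as.integer(n), as.integer(seed))
  as_fastx_tbl(x[idx, , drop = FALSE])
}
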