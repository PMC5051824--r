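# Independent oracles, written from first principles and kept deliberately
# separate from the implementation they check.

# reverse complement via an explicit pairing dictionary: reverse the string,
# then map each letter through the table
rc_oracle <- function(s) {
  pairs <- c(
    A = "T", T = "A", C = "G", G = "C",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", V = "B", D = "H", H = "D", N = "N",
    a = "t", t = "a", c = "g", g = "c",
    r = "y", y = "r", s = "s", w = "w", k = "m", m = "k",
    b = "v", v = "b", d = "h", h = "d", n = "n",
    "-" = "-", "." = "."
  )
  chars <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
  paste(pairs[chars], collapse = "")
}

# expand a degenerate motif into the set of concrete strings it denotes
degen_expand <- function(motif) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T", U = "U",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
    D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  out <- ""
  for (ch in chars) out <- as.vector(outer(out, sets[[ch]], paste0))
  out
}

# test every start offset of seq against every expansion of the motif
brute_locate <- function(seq, motif) {
  expansions <- degen_expand(motif)
  m <- nchar(motif)
  L <- nchar(seq)
  starts <- integer(0)
  if (L >= m) {
    for (st in seq_len(L - m + 1L)) {
      if (substr(seq, st, st + m - 1L) %in% expansions) starts <- c(starts, st)
    }
  }
  starts
}

# negative-index region rule applied directly to the materialised index list
region_oracle <- function(L, s, e) {
  idx <- seq_len(L)
  map1 <- function(v) if (v < 0L) L + v + 1L else v
  s2 <- min(max(map1(s), 1L), L)
  e2 <- min(max(map1(e), 1L), L)
  if (s2 > e2) return(NULL)
  idx[s2:e2]
}

# write records to a temporary FASTA/FASTQ file and return the path
tmp_fastx <- function(x, ext = ".fa", line_width = 60L) {
  f <- tempfile(fileext = ext)
  write_fastx(x, f, line_width = line_width)
  f
}

expect_same_records <- function(a, b) {
  expect_identical(a$header, b$header)
  expect_identical(a$seq, b$seq)
  expect_identical(a$qual, b$qual)
}
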