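test_that("format autodetection reads the first record delimiter", {
  fa <- tempfile(); writeLines(c(">s1", "ACGT"), fa)
  fq <- tempfile(); writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  bad <- tempfile(); writeLines("xACGT", bad)
  empty <- tempfile(); file.create(empty)
  expect_identical(fastx_detect_format(fa), "fasta")
  expect_identical(fastx_detect_format(fq), "fastq")
  expect_error(fastx_detect_format(bad), class = "fastx_malformed_error")
  expect_identical(fastx_detect_format(empty), NA_character_)
  expect_identical(nrow(read_fastx(empty)), 0L)
})

test_that("parser concatenates multi-line records and extracts IDs", {
  f <- tempfile()
  writeLines(c(">s1 some desc", "ACGT", ">s2", "AC", "GT"), f)
  x <- read_fastx(f)
  expect_identical(x$id, c("s1", "s2"))
  expect_identical(x$header, c("s1 some desc", "s2"))
  expect_identical(x$seq, c("ACGT", "ACGT"))
  expect_true(all(is.na(x$qual)))

  # multi-line FASTQ: sequence and quality both concatenated
  fq <- tempfile()
  writeLines(c("@r1", "ACGTAC", "GT", "+", "IIIIII", "II"), fq)
  y <- read_fastx(fq)
  expect_identical(y$seq, "ACGTACGT")
  expect_identical(y$qual, "IIIIIIII")
  # round-trip identity for the hand-constructed record
  z <- read_fastx(tmp_fastx(y, ext = ".fq"))
  expect_same_records(y, z)
})

test_that("custom ID patterns drive ID extraction", {
  f <- tempfile()
  writeLines(c(">gi|123|ref gene", "ACGT"), f)
  expect_identical(read_fastx(f)$id, "gi|123|ref")
  expect_identical(read_fastx(f, id_pattern = "^gi\\|(\\d+)\\|")$id, "123")
})

test_that("malformed FASTQ records are rejected with record context", {
  f <- tempfile()
  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_fastx(f), class = "fastx_malformed_error")
  g <- tempfile()
  writeLines(c("@r1", "ACGT", "+"), g)
  expect_error(read_fastx(g), class = "fastx_malformed_error")
  h <- tempfile()
  writeLines(c("@r1", "ACGT"), h)
  expect_error(read_fastx(h), class = "fastx_malformed_error")
})

test_that("CRLF line endings are stripped on read", {
  f <- tempfile()
  con <- file(f, "wb")
  writeLines(c(">s1 d", "ACGT"), con, sep = "\r\n")
  close(con)
  x <- read_fastx(f)
  expect_identical(x$header, "s1 d")
  expect_identical(x$seq, "ACGT")
})

test_that("writer wraps FASTA at line_width and never wraps FASTQ", {
  x <- fastx_tbl(id = "s", seq = paste(rep("A", 130), collapse = ""))
  f <- tmp_fastx(x, line_width = 60L)
  lines <- readLines(f)
  expect_identical(nchar(lines[-1L]), c(60L, 60L, 10L))
  f0 <- tmp_fastx(x, line_width = 0L)
  expect_length(readLines(f0), 2L)

  q <- sim_fastx(3, len_min = 150, len_max = 150, format = "fastq", seed = 5)
  expect_length(readLines(tmp_fastx(q, ext = ".fq")), 12L)
  # FASTQ output requires qualities
  expect_error(write_fastx(fastx_tbl(id = "a", seq = "AC"), tempfile(), format = "fastq"),
    class = "fastx_format_error"
  )
})

test_that("parse-write round trips preserve records exactly", {
  cases <- list(
    sim_fastx(40, len_min = 10, len_max = 200, seed = 1),
    sim_fastx(40, len_min = 10, len_max = 200, format = "fastq", seed = 2),
    sim_fastx(10, len_min = 5, len_max = 15, alphabet = "protein", seed = 3)
  )
  for (x in cases) {
    for (ext in c(".fa", ".fa.gz")) {
      if (ext == ".fa.gz" && any(!is.na(x$qual))) next
      for (w in c(0L, 13L, 60L)) {
        y <- read_fastx(tmp_fastx(x, ext = ext, line_width = w))
        expect_same_records(x, y)
      }
    }
  }
  # gzip twin parses identically to the plain file, and the .gz starts with
  # the gzip magic bytes
  x <- cases[[1L]]
  gz <- tmp_fastx(x, ext = ".fa.gz")
  expect_identical(readBin(gz, "raw", 2L), as.raw(c(0x1f, 0x8b)))
  expect_same_records(read_fastx(gz), x)
})

test_that("fx2tab computes lengths and GC; tab2fx inverts it", {
  x <- fastx_tbl(id = "s1", seq = "ACGC")
  tab <- fx2tab(x, add_length = TRUE, add_gc = TRUE)
  expect_identical(tab$length, 4L)
  expect_identical(tab$gc, 75)
  expect_identical(fx2tab(fastx_tbl(id = "e", seq = ""), add_gc = TRUE)$gc, 0)
  expect_identical(fx2tab(fastx_tbl(id = "s", seq = "ACGTACGT"), add_length = TRUE)$length, 8L)
  # S counts toward GC
  expect_identical(gc_percent("ASgc"), 75)

  y <- sim_fastx(100, len_min = 10, len_max = 50, format = "fastq", seed = 9)
  expect_same_records(tab2fx(fx2tab(y)), y)
  f <- tempfile()
  writeLines(c("s1\tACGT", "r1 x\tGGCC"), f)
  z <- tab2fx(f)
  expect_identical(z$id, c("s1", "r1"))
  bad <- tempfile(); writeLines("only_one_column", bad)
  expect_error(tab2fx(bad), class = "fastx_malformed_error")
})

test_that("fq2fa drops qualities and preserves headers byte for byte", {
  x <- sim_fastx(20, len_min = 10, len_max = 30, format = "fastq", seed = 4)
  x$header <- paste(x$header, "description text")
  y <- fq2fa(x)
  expect_identical(nrow(y), nrow(x))
  expect_identical(y$header, x$header)
  expect_identical(y$seq, x$seq)
  expect_true(all(is.na(y$qual)))
  expect_warning(fq2fa(y), "already FASTA")
})

test_that("stats are exact and empty input yields zeros", {
  lens <- c(1L, 2L, 3L)
  x <- fastx_tbl(id = paste0("s", lens), seq = strrep("A", lens))
  st <- fastx_stats(x)
  expect_identical(st$num_seqs, 3L)
  expect_identical(st$sum_len, 6)
  expect_identical(st$min_len, 1)
  expect_identical(st$avg_len, 2)
  expect_identical(st$max_len, 3)
  st1 <- fastx_stats(fastx_tbl(id = "a", seq = strrep("C", 10)))
  expect_identical(unlist(st1), c(num_seqs = 1, sum_len = 10, min_len = 10, avg_len = 10, max_len = 10))
  st0 <- fastx_stats(fastx_tbl())
  expect_identical(unlist(st0), c(num_seqs = 0, sum_len = 0, min_len = 0, avg_len = 0, max_len = 0))
  # streaming path over a file agrees with the in-memory path
  f <- tmp_fastx(x)
  expect_identical(fastx_stats(f), st)
  expect_identical(glance(x), st)
})

test_that("head returns the first records and stops consuming the stream", {
  x <- sim_fastx(10, len_min = 5, len_max = 5, seed = 6)
  expect_same_records(fastx_head(x, 3), x[1:3, ])
  expect_identical(nrow(fastx_head(x, 0)), 0L)
  expect_same_records(fastx_head(x, 99), x)
  expect_error(fastx_head(x, -1), class = "fastx_usage_error")

  # a malformed record beyond the first n must never be reached
  f <- tempfile()
  writeLines(c("@r1", "AC", "+", "II", "@r2", "AC", "+", "II", "@r3", "ACGT", "+", "I"), f)
  expect_identical(fastx_head(f, 2)$id, c("r1", "r2"))
  expect_error(read_fastx(f), class = "fastx_malformed_error")
})
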