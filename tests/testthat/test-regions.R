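test_that("region notation resolves like the worked examples", {
  expect_identical(resolve_region(100, "1:-1"), c(1L, 100L))
  expect_identical(resolve_region(100, "-12:-1"), c(89L, 100L))
  expect_identical(resolve_region(100, "1:20"), c(1L, 20L))
  # out-of-range endpoints clamp rather than error
  expect_identical(resolve_region(5, "3:100"), c(3L, 5L))
  expect_identical(resolve_region(5, "-100:-1"), c(1L, 5L))
  expect_error(resolve_region(10, "5:2"), class = "fastx_region_error")
  expect_error(resolve_region(10, "0:3"), class = "fastx_region_error")
  expect_error(parse_region("abc"), class = "fastx_region_error")
})

test_that("resolve_region agrees with the materialised-index oracle", {
  for (L in c(1L, 2L, 3L, 7L, 20L, 50L)) {
    ends <- setdiff(seq.int(-(L + 5L), L + 5L), 0L)
    for (s in ends) {
      for (e in ends) {
        oracle <- region_oracle(L, s, e)
        got <- tryCatch(resolve_region(L, list(start = s, end = e)), error = function(x) NULL)
        if (is.null(oracle)) {
          expect_null(got)
        } else {
          expect_identical(got, c(oracle[[1L]], oracle[[length(oracle)]]))
        }
      }
    }
  }
})

test_that("subseq slices sequence and quality together and annotates headers", {
  x <- fastx_tbl(id = "s1", seq = "ACGTACGT")
  y <- fastx_subseq(x, "2:4")
  expect_identical(y$seq, "CGT")
  expect_identical(y$header, "s1_2-4")
  q <- fastx_tbl(id = "r1", seq = "ACGTACGT", qual = "ABCDEFGH")
  yq <- fastx_subseq(q, "2:4")
  expect_identical(yq$qual, "BCD")
  expect_identical(fastx_subseq(x, "1:-1")$seq, x$seq)
  # output length always matches the resolved window
  withr::with_seed(12, {
    for (i in 1:50) {
      L <- sample(1:30, 1)
      s <- sample(setdiff(-(L + 5):(L + 5), 0), 1)
      e <- sample(setdiff(-(L + 5):(L + 5), 0), 1)
      rec <- sim_fastx(1, len_min = L, len_max = L, seed = i)
      se <- tryCatch(resolve_region(L, list(start = s, end = e)), error = function(x) NULL)
      if (is.null(se)) next
      out <- fastx_subseq(rec, sprintf("%d:%d", s, e))
      expect_identical(nchar(out$seq), se[[2L]] - se[[1L]] + 1L)
    }
  })
})

test_that("BED features extract with half-open convention and strand", {
  x <- fastx_tbl(id = "c1", seq = "ACGTACGT")
  bed <- tempfile()
  writeLines(c("# comment", "c1\t0\t4"), bed)
  y <- fastx_subseq_features(x, read_bed(bed))
  expect_identical(y$seq, "ACGT")
  # minus strand: reverse complement of the plus-strand slice
  bed2 <- tempfile()
  writeLines("c1\t0\t3\tf1\t0\t-", bed2)
  y2 <- fastx_subseq_features(x, read_bed(bed2))
  expect_identical(y2$seq, "CGT")  # revcomp("ACG")
  # unknown chrom skipped with a warning
  bed3 <- tempfile()
  writeLines(c("c1\t0\t2", "nope\t0\t2"), bed3)
  expect_warning(y3 <- fastx_subseq_features(x, read_bed(bed3)), "skipped 1")
  expect_identical(nrow(y3), 1L)
})

test_that("GTF features extract with 1-based convention, flanks clip at bounds", {
  x <- fastx_tbl(id = "c1", seq = "ACGTACGTAC")
  gtf <- tempfile()
  writeLines("c1\tsrc\texon\t1\t4\t.\t+\t.\tgene_id \"g1\";", gtf)
  feats <- read_gtf(gtf)
  expect_identical(feats$name, "g1")
  # upstream=2 clips at base 1, so bases 1-4 come back
  y <- fastx_subseq_features(x, feats, upstream = 2)
  expect_identical(y$seq, "ACGT")
  # flanks follow strand orientation: upstream of a minus-strand feature
  # extends to higher coordinates
  gtf2 <- tempfile()
  writeLines("c1\tsrc\texon\t3\t5\t.\t-\t.\tgene_id \"g2\";", gtf2)
  y2 <- fastx_subseq_features(x, read_gtf(gtf2), upstream = 2)
  # plus-strand interval 3..7 = "GTACG", minus output = revcomp
  expect_identical(y2$seq, rc_oracle("GTACG"))
  # only_flank excludes the body
  y3 <- fastx_subseq_features(x, read_gtf(gtf2), upstream = 2, only_flank = TRUE)
  expect_identical(y3$seq, rc_oracle("CG"))  # bases 6..7 on plus strand
})

test_that("minus-strand extraction equals revcomp of plus-strand extraction", {
  x <- sim_fastx(1, len_min = 40, len_max = 40, prefix = "chr", seed = 33)
  for (i in 1:20) {
    s <- ((7 * i) %% 30) + 1L
    e <- min(40L, s + (i %% 9))
    plus <- tibble::tibble(chrom = x$id, start = s, end = e, strand = "+", name = NA_character_)
    minus <- dplyr::mutate(plus, strand = "-")
    a <- fastx_subseq_features(x, plus)$seq
    b <- fastx_subseq_features(x, minus)$seq
    expect_identical(b, rc_oracle(a))
  }
})

test_that("sliding windows enumerate exactly the fitting starts", {
  x <- fastx_tbl(id = "s", seq = strrep("ACGTA", 2))  # length 10
  w <- fastx_sliding(x, window = 5, step = 5)
  expect_identical(w$header, c("s:1-5", "s:6-10"))
  expect_identical(nchar(w$seq), c(5L, 5L))
  expect_identical(nrow(fastx_sliding(fastx_tbl(id = "t", seq = "ACGT"), 5, 1)), 0L)
  one <- fastx_sliding(fastx_tbl(id = "t", seq = "ACGT"), 4, 1)
  expect_identical(one$header, "t:1-4")
  expect_error(fastx_sliding(x, 0, 1), class = "fastx_usage_error")

  # enumeration oracle over all start positions
  rec <- sim_fastx(1, len_min = 23, len_max = 23, seed = 9)
  for (win in c(1L, 4L, 7L)) {
    for (st in c(1L, 3L, 5L)) {
      got <- fastx_sliding(rec, win, st)
      starts <- seq.int(1L, 23L, by = st)
      starts <- starts[starts + win - 1L <= 23L]
      expect_identical(nrow(got), length(starts))
      expect_identical(got$seq, substring(rec$seq, starts, starts + win - 1L))
      if (length(starts) > 1L) expect_true(all(diff(starts) == st))
    }
  }
  # circular windows wrap and qualities co-slice
  q <- fastx_tbl(id = "r", seq = "ACGT", qual = "WXYZ")
  cw <- fastx_sliding(q, window = 3, step = 2, circular = TRUE)
  expect_identical(cw$seq, c("ACG", "GTA"))
  expect_identical(cw$qual, c("WXY", "YZW"))
})
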