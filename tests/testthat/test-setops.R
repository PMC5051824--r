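test_that("rmdup keeps first occurrences and counts collisions", {
  x <- fastx_tbl(id = c("a", "b", "c"), seq = c("ACGT", "ACGT", "CCCC"))
  y <- fastx_rmdup(x, by = "seq")
  expect_identical(y$id, c("a", "c"))
  expect_identical(attr(y, "removed"), 1L)
  expect_identical(attr(y, "dups")$id, "b")
  # case folding collapses acgt/ACGT iff requested; the digests themselves agree
  z <- fastx_tbl(id = c("u", "l"), seq = c("ACGT", "acgt"))
  expect_identical(nrow(fastx_rmdup(z, by = "seq")), 2L)
  expect_identical(nrow(fastx_rmdup(z, by = "seq", ignore_case = TRUE)), 1L)
  expect_identical(cli::hash_md5("ACGT"), cli::hash_md5(toupper("acgt")))
  # all-unique input is untouched
  u <- sim_fastx(20, seed = 3)
  expect_identical(attr(fastx_rmdup(u, by = "seq"), "removed"), 0L)
  # duplicates optionally saved to a file
  dupf <- tempfile(fileext = ".fa")
  fastx_rmdup(x, by = "seq", save_dups = dupf)
  expect_identical(read_fastx(dupf)$id, "b")
})

test_that("digest-keyed rmdup equals whole-sequence-comparison rmdup", {
  x <- sim_fastx(100, len_min = 30, len_max = 60, dup_fraction = 0.2, seed = 21)
  by_digest <- fastx_rmdup(x, by = "seq")
  by_content <- x[!duplicated(x$seq), ]
  expect_identical(by_digest$id, by_content$id)
  # idempotence: kept + removed = total, second pass removes nothing
  expect_identical(nrow(by_digest) + attr(by_digest, "removed"), nrow(x))
  again <- fastx_rmdup(by_digest, by = "seq")
  expect_identical(attr(again, "removed"), 0L)
  expect_identical(again$id, by_digest$id)
})

test_that("common finds first-file records present in every other file", {
  a <- fastx_tbl(id = c("a", "b", "c"), seq = c("AA", "CC", "GG"))
  b <- fastx_tbl(id = c("b", "c", "d"), seq = c("TT", "AA", "CC"))
  got <- fastx_common(list(a, b))
  expect_identical(got$id, c("b", "c"))
  # disjoint inputs give empty output
  d <- fastx_tbl(id = c("x", "y"), seq = c("AA", "CC"))
  expect_identical(nrow(fastx_common(list(a, d))), 0L)
  # by=seq compares content regardless of headers
  e <- fastx_tbl(id = c("other1", "other2"), seq = c("GG", "AA"))
  expect_identical(fastx_common(list(a, e), by = "seq")$id, c("a", "c"))
  expect_error(fastx_common(list(a)), class = "fastx_usage_error")
  # file paths work too, three-way
  fa <- tmp_fastx(a); fb <- tmp_fastx(b); fc <- tmp_fastx(a[2:3, ])
  expect_identical(fastx_common(list(fa, fb, fc))$id, c("b", "c"))
})

test_that("split partitions records in each of the four modes", {
  x <- sim_fastx(10, len_min = 8, len_max = 8, seed = 14)
  dir_size <- withr::local_tempdir()
  man <- fastx_split(x, by_size = 3, out_dir = dir_size)
  expect_identical(man$n, c(3L, 3L, 3L, 1L))
  dir_part <- withr::local_tempdir()
  man2 <- fastx_split(x, by_part = 2, out_dir = dir_part)
  expect_identical(man2$n, c(5L, 5L))
  # by id: one file per distinct ID
  y <- fastx_tbl(id = c("x", "x", "y"), seq = c("AA", "CC", "GG"))
  dir_id <- withr::local_tempdir()
  man3 <- fastx_split(y, by_id = TRUE, out_dir = dir_id)
  expect_identical(man3$n, c(2L, 1L))
  expect_identical(read_fastx(man3$file[[1L]])$seq, c("AA", "CC"))
  # by region: grouping key is the upper-folded subsequence
  z <- fastx_tbl(id = c("p", "q", "r"), seq = c("ACGT", "acTT", "ACAA"))
  dir_reg <- withr::local_tempdir()
  man4 <- fastx_split(z, by_region = "1:2", out_dir = dir_reg)
  expect_identical(man4$key, "AC")
  expect_identical(man4$n, 3L)

  # every mode partitions the input exactly
  big <- sim_fastx(37, len_min = 10, len_max = 20, seed = 8)
  for (mode in list(list(by_size = 5), list(by_part = 4), list(by_id = TRUE), list(by_region = "1:2"))) {
    d <- withr::local_tempdir()
    man <- do.call(fastx_split, c(list(x = big, out_dir = d), mode))
    back <- dplyr::bind_rows(lapply(man$file, read_fastx))
    expect_identical(sort(back$header), sort(big$header))
    expect_identical(nrow(back), nrow(big))
    expect_identical(sum(man$n), nrow(big))
  }
  expect_error(fastx_split(x, by_size = 0, out_dir = tempdir()), class = "fastx_usage_error")
  expect_error(fastx_split(x, out_dir = tempdir()), class = "fastx_usage_error")
})

test_that("sampling is seeded, order-preserving and exact at the edges", {
  x <- sim_fastx(1000, len_min = 10, len_max = 10, seed = 2)
  expect_identical(fastx_sample(x, p = 1.0, seed = 5)$id, x$id)
  expect_identical(fastx_sample(x, n = 2000, seed = 5)$id, x$id)
  s1 <- fastx_sample(x, n = 100, seed = 42)
  s2 <- fastx_sample(x, n = 100, seed = 42)
  expect_identical(s1$id, s2$id)
  expect_identical(nrow(s1), 100L)
  # output preserves relative input order
  expect_false(is.unsorted(match(s1$id, x$id)))
  s3 <- fastx_sample(x, n = 100, seed = 43)
  expect_false(identical(s1$id, s3$id))
  expect_error(fastx_sample(x, n = 5, p = 0.5), class = "fastx_usage_error")
  expect_error(fastx_sample(x), class = "fastx_usage_error")
  expect_error(fastx_sample(x, p = 1.5), class = "fastx_usage_error")
})

test_that("proportion sampling keeps a binomially plausible count", {
  x <- sim_fastx(10000, len_min = 5, len_max = 5, seed = 7)
  kept <- nrow(fastx_sample(x, p = 0.1, seed = 99))
  # 3 sigma around np: sigma = sqrt(10000 * 0.1 * 0.9) = 30
  expect_gt(kept, 1000 - 90)
  expect_lt(kept, 1000 + 90)
})

test_that("number-mode sampling is uniform over records", {
  x <- fastx_tbl(id = paste0("r", 1:5), seq = strrep("A", 5:9))
  counts <- stats::setNames(numeric(5), x$id)
  for (seed in 1:2000) {
    s <- fastx_sample(x, n = 2, seed = seed)
    counts[s$id] <- counts[s$id] + 1
  }
  freq <- counts / 2000
  # each record appears with probability 2/5; 4 sigma on a frequency
  sigma <- sqrt(0.4 * 0.6 / 2000)
  expect_true(all(abs(freq - 0.4) < 4 * sigma))
})
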