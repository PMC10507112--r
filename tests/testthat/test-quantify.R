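test_that("quality filter keeps exactly the reads a brute-force recount keeps", {
  set.seed(31)
  n <- 200
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                             collapse = ""))
  quals <- replicate(n, intToUtf8(33 + sample(0:40, 30, TRUE)))
  batch <- batch_of(seqs, quals)
  kept <- suppressMessages(filter_reads(batch, min_mean_q = 20))
  oracle <- vapply(quals, function(q) mean(utf8ToInt(q) - 33) >= 20, TRUE)
  expect_equal(nrow(kept), sum(oracle))
  expect_identical(kept$sequence, seqs[oracle])
})

test_that("all-high and all-low quality batches filter trivially", {
  b_hi <- batch_of(rep("ACGT", 5), rep("IIII", 5))   # Q40
  b_lo <- batch_of(rep("ACGT", 5), rep("!!!!", 5))   # Q0
  expect_equal(nrow(suppressMessages(filter_reads(b_hi))), 5)
  expect_equal(nrow(suppressMessages(filter_reads(b_lo))), 0)
  bad <- batch_of("ACGT", "III")
  expect_error(suppressMessages(filter_reads(bad)), "length")
})

test_that("demultiplexing assigns exact barcodes and conserves reads", {
  bc <- c(s1 = "AAAAAAAA", s2 = "CCCCCCCC")
  reads <- batch_of(c("AAAAAAAATTTT", "CCCCCCCCTTTT", "GGGGGGGGTTTT",
                      "AAAAAAATTTTT"),
                    rep("IIIIIIIIIIII", 4))
  out <- demultiplex_reads(reads, bc)
  expect_equal(out$sample, c("s1", "s2", NA, NA))
  asn <- attr(out, "assignment")
  expect_equal(sum(asn$reads), nrow(reads))
  # 1 substitution stays unassigned in strict mode but rescues at mm = 1
  out1 <- demultiplex_reads(reads, bc, max_mismatch = 1)
  expect_equal(out1$sample[4], "s1")
})

test_that("ambiguous barcode pairs are a configuration error", {
  bc <- c(s1 = "AAAAAAAA", s2 = "AAAAAAAC")
  reads <- batch_of("AAAAAAAATT", "IIIIIIIIII")
  expect_error(demultiplex_reads(reads, bc, max_mismatch = 1), "ambiguous")
})

test_that("guide counting is exact-match with anchored location", {
  lib <- tiny_library(4, 2, seed = 21)
  g <- lib$sequence[1]
  flank5 <- "TTGTGGAAAGGACGAAACACCG"
  read_ok <- paste0("AAAAAAAA", flank5, g, "GTTT")
  mut <- g
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(g, 5, 5))[1]
  read_mut <- paste0("AAAAAAAA", flank5, mut, "GTTT")
  batch <- batch_of(c(read_ok, read_mut), rep(strrep("I", nchar(read_ok)), 2))
  cv <- suppressMessages(count_guides(batch, lib))
  expect_equal(cv$count[1], 1)
  expect_equal(sum(cv$count), 1)
  expect_equal(attr(cv, "unmapped"), 1)
  # 1-mismatch rescue recovers the mutated guide
  cv1 <- suppressMessages(count_guides(batch, lib, max_mismatch = 1))
  expect_equal(cv1$count[1], 2)
})

test_that("mapped plus unmapped equals filtered reads, order-invariantly", {
  lib <- tiny_library(10, 10, seed = 22)
  cnt <- simulate_screen_counts(lib, depth = 1000, dispersion = 0,
                                n_replicates = 1, seed = 23)
  f <- withr::local_tempfile(fileext = ".fastq")
  fq <- write_amplicon_fastq(cnt, lib, f, seed = 24)
  batch <- read_amplicon_fastq(f)
  cv <- suppressMessages(count_guides(batch, lib))
  expect_equal(sum(cv$count) + attr(cv, "unmapped"), nrow(batch))
  shuffled <- batch[sample.int(nrow(batch)), ]
  cv2 <- suppressMessages(count_guides(shuffled, lib))
  expect_identical(cv$count, cv2$count)
})
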