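test_that("pseudocount log2 fold-change matches hand arithmetic", {
  x <- tibble::tibble(guide_id = c("g1", "g2", "g3"),
                      sel = c(96L, 0L, 32L), ref = c(32L, 0L, 96L))
  raw <- guide_lfc(x, "sel", "ref", median_center = FALSE)
  expect_equal(raw$lfc[1], log2(128 / 64))  # = 1
  expect_equal(raw$lfc[2], 0)               # zeros well-defined via pc 32
  expect_equal(raw$lfc[3], -1)
  centered <- guide_lfc(x, "sel", "ref")
  expect_equal(centered$lfc, raw$lfc - median(raw$lfc))
  expect_error(guide_lfc(tibble::tibble(guide_id = "g", sel = -1L, ref = 1L),
                         "sel", "ref"), "Negative")
})

test_that("identical samples give all-zero centered lfc", {
  x <- tibble::tibble(guide_id = paste0("g", 1:5),
                      a = c(10L, 50L, 0L, 7L, 100L))
  x$b <- x$a
  expect_true(all(guide_lfc(x, "a", "b")$lfc == 0))
})

test_that("normalize_and_average handles identity, flip, and scaling", {
  lfc <- tibble::tibble(guide_id = paste0("g", 1:6),
                        m1 = c(-2, -1, 0, 1, 2, 3))
  # single column, no options: identity
  expect_equal(normalize_and_average(lfc)$score, lfc$m1)
  # x and -x with the second flipped average back to x
  lfc2 <- dplyr::mutate(lfc, m2 = -m1)
  out <- normalize_and_average(lfc2, flip = "m2")
  expect_equal(out$score, lfc$m1)
  # unit-variance scaling equalises column sds (independent recompute)
  lfc3 <- tibble::tibble(guide_id = paste0("g", 1:50),
                         a = rnorm(50, sd = 2), b = rnorm(50, sd = 0.5))
  scaled_a <- lfc3$a / sd(lfc3$a)
  scaled_b <- lfc3$b / sd(lfc3$b)
  out3 <- normalize_and_average(lfc3, scale_unit_variance = TRUE)
  expect_equal(out3$score, (scaled_a + scaled_b) / 2)
})

test_that("scaling rejects zero-variance columns by name", {
  lfc <- tibble::tibble(guide_id = c("g1", "g2"), ok = c(1, 2),
                        flat = c(3, 3))
  expect_error(normalize_and_average(lfc, scale_unit_variance = TRUE),
               "flat")
})

test_that("rescaling one column is absorbed by unit-variance scaling", {
  set.seed(5)
  lfc <- tibble::tibble(guide_id = paste0("g", 1:40),
                        a = rnorm(40), b = rnorm(40))
  out1 <- normalize_and_average(lfc, scale_unit_variance = TRUE)
  lfc$b <- lfc$b * 7
  out2 <- normalize_and_average(lfc, scale_unit_variance = TRUE)
  expect_equal(out1$score, out2$score)
})

test_that("gene_score equals a brute-force group-by mean and drops controls", {
  lib <- tiny_library(8, 12, seed = 31)
  set.seed(32)
  gs <- tibble::tibble(guide_id = lib$guide_id, score = rnorm(nrow(lib)))
  genes <- gene_score(gs, lib)
  oracle <- tapply(gs$score[lib$gene != "control"],
                   lib$gene[lib$gene != "control"], mean)
  expect_equal(genes$score, as.numeric(oracle[genes$gene]))
  expect_false("control" %in% genes$gene)
  expect_true(all(genes$n_guides == 3))
  # simple arithmetic case
  lib1 <- simulate_guide_library(1, n_controls = 0, seed = 1)
  gs1 <- tibble::tibble(guide_id = lib1$guide_id, score = c(1, 2, 3))
  expect_equal(gene_score(gs1, lib1)$score, 2)
})
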