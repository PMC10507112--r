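test_that("score_screen recovers a strong hit end to end", {
  lib <- simulate_guide_library(60, n_controls = 100, seed = 51)
  eff <- gene_effects(lib, c(GENE00005 = -2, GENE00010 = 1.5))
  cnt <- simulate_screen_counts(lib, eff, depth = 2e5, n_replicates = 3,
                                seed = 52)
  res <- score_screen(cnt, lib, n_perm = 10000, seed = 53)
  g <- res$genes
  expect_lt(g$q[g$gene == "GENE00005"], 0.05)
  expect_lt(g$q[g$gene == "GENE00010"], 0.05)
  expect_equal(g$direction[g$gene == "GENE00005"], -1L)
  expect_equal(g$direction[g$gene == "GENE00010"], 1L)
  expect_true(all(g$q >= g$p))
  expect_false("control" %in% g$gene)
  expect_equal(nrow(g), 60)
})

test_that("a depleting migration gene scores negative from both populations", {
  lib <- simulate_guide_library(40, n_controls = 80, seed = 54)
  eff <- gene_effects(lib, c(GENE00003 = -1.5, GENE00007 = 1))
  cnt <- simulate_screen_counts(lib, eff, screen = "migration",
                                depth = 5e5, n_replicates = 4, seed = 55)
  # score the migratory and (flipped) non-migratory measurements separately
  design <- screen_design(cnt)
  lfc_of_role <- function(role, flip) {
    cols <- list(guide_id = cnt$guide_id)
    for (r in unique(design$replicate)) {
      num <- design$sample[design$role == role & design$replicate == r]
      ref <- design$sample[design$role == "reference" & design$replicate == r]
      cols[[paste0("m", r)]] <- guide_lfc(cnt, num, ref)$lfc
    }
    lfc <- tibble::as_tibble(cols)
    normalize_and_average(lfc, scale_unit_variance = TRUE,
                          flip = if (flip) setdiff(names(lfc), "guide_id"))
  }
  g_mig <- gene_score(lfc_of_role("migratory", FALSE), lib)
  g_non <- gene_score(lfc_of_role("non_migratory", TRUE), lib)
  for (gene in c("GENE00003", "GENE00007")) {
    expect_equal(sign(g_mig$score[g_mig$gene == gene]),
                 sign(g_non$score[g_non$gene == gene]))
  }
  expect_lt(g_mig$score[g_mig$gene == "GENE00003"], 0)
  expect_gt(g_mig$score[g_mig$gene == "GENE00007"], 0)
  # the full pipeline averages both populations
  res <- score_screen(cnt, lib, n_perm = 5000, seed = 56)
  expect_equal(res$genes$n_measurements[1], 8)
  expect_lt(res$genes$score[res$genes$gene == "GENE00003"], 0)
})

test_that("compare_screens: self-correlation 1, independent nulls near 0", {
  lib <- simulate_guide_library(400, n_controls = 100, seed = 57)
  mk <- function(seed) {
    cnt <- simulate_screen_counts(lib, depth = 1e5, n_replicates = 2,
                                  seed = seed)
    score_screen(cnt, lib, n_perm = 2000, seed = seed + 1)
  }
  a <- mk(58); b <- mk(60)
  expect_equal(compare_screens(a, a)$correlation, 1)
  cmp <- compare_screens(a, b)
  expect_lt(abs(cmp$correlation), 0.15)
  expect_equal(sum(cmp$overlap$n_genes), cmp$n_shared)
})

test_that("screen_overlap partitions the union of significant sets", {
  lib <- simulate_guide_library(50, n_controls = 80, seed = 61)
  eff <- gene_effects(lib, c(GENE00001 = -2, GENE00002 = -2))
  cnt1 <- simulate_screen_counts(lib, eff, depth = 2e5, seed = 62)
  cnt2 <- simulate_screen_counts(lib, eff, depth = 2e5, seed = 63)
  r1 <- score_screen(cnt1, lib, n_perm = 5000, seed = 64)
  r2 <- score_screen(cnt2, lib, n_perm = 5000, seed = 65)
  ov <- screen_overlap(list(s1 = r1, s2 = r2))
  union_size <- length(union(r1$genes$gene[r1$genes$q < 0.05],
                             r2$genes$gene[r2$genes$q < 0.05]))
  expect_equal(sum(ov$n_genes), union_size)
})

test_that("migration fraction arithmetic", {
  expect_equal(migration_fraction(30, 70), 0.30)
  expect_equal(migration_fraction(0, 50), 0)
  expect_equal(migration_fraction(6, 94), 0.06)
  expect_error(migration_fraction(0, 0), "undefined")
  expect_error(migration_fraction(-1, 5), "non-negative")
})
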