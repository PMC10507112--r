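test_that("the screen demo runs, calibrates, and reproduces per seed", {
  dir1 <- withr::local_tempdir()
  out <- suppressMessages(run_screen_demo(
    dir1, n_genes = 60, n_controls = 120, n_hits = 8, effect = -1.5,
    depth = 2e4, n_perm = 4000, seed = 7))
  expect_true(file.exists(file.path(dir1, "gene_results.tsv")))
  expect_true(file.exists(file.path(dir1, "config.yaml")))
  expect_true(file.exists(file.path(dir1, "calibration.yaml")))
  expect_gte(out$calibration$n_hits_recovered, 7)  # >= all but one hit
  expect_lte(out$calibration$frac_null_q_below_0.05, 0.07)
  dir2 <- withr::local_tempdir()
  suppressMessages(run_screen_demo(
    dir2, n_genes = 60, n_controls = 120, n_hits = 8, effect = -1.5,
    depth = 2e4, n_perm = 4000, seed = 7))
  expect_identical(readLines(file.path(dir1, "gene_results.tsv")),
                   readLines(file.path(dir2, "gene_results.tsv")))
})

test_that("the tracking demo separates persistence phenotypes", {
  dir <- withr::local_tempdir()
  out <- suppressMessages(run_tracking_demo(
    dir, n_cells = 8, n_steps = 50, q = c(0.2, 0.7), a = 0.2,
    grid = hrw_grid(grid_size = 60), seed = 11))
  expect_true(file.exists(file.path(dir, "per_cell.tsv")))
  expect_true(file.exists(file.path(dir, "truth_vs_estimate.tsv")))
  expect_lt(out$comparison$p_value, 0.01)
  rep1 <- out$report
  expect_lt(abs(rep1$mean_q[1] - 0.2), 0.25)
  expect_lt(abs(rep1$mean_q[2] - 0.7), 0.25)
})

test_that("tidiers and plots produce the documented shapes", {
  lib <- tiny_library(10, 30, seed = 151)
  cnt <- simulate_screen_counts(lib, depth = 2e4, n_replicates = 2,
                                seed = 152)
  res <- score_screen(cnt, lib, n_perm = 1000, seed = 153)
  td <- tidy(res)
  expect_named(td, c("gene", "score", "p", "q", "direction", "n_guides",
                     "n_measurements"))
  gl <- glance(res)
  expect_equal(gl$n_genes, 10)
  expect_s3_class(autoplot(res), "ggplot")

  tr <- simulate_tracks(3, 40, q = 0.5, a = 0.2, seed = 154)
  expect_s3_class(autoplot(tr), "ggplot")
  fit <- infer_persistence(tr, grid = hrw_grid(grid_size = 40))
  expect_named(tidy(fit), c("cell", "mean_q", "mean_a", "n_steps"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_msd(tr), "ggplot")

  fl <- simulate_flow(500, seed = 155)
  ax <- differentiation_axis(fl)
  expect_named(tidy(ax), c("channel", "loading", "center"))
  expect_equal(glance(ax)$n_events, 500)
  expect_s3_class(autoplot(ax), "ggplot")
})

test_that("counts round-trip through TSV with their design", {
  lib <- tiny_library(4, 6, seed = 161)
  cnt <- simulate_screen_counts(lib, depth = 1000, n_replicates = 2,
                                seed = 162)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_screen_counts(cnt, f)
  back <- read_screen_counts(f)
  expect_equal(tibble::as_tibble(as.data.frame(back)),
               tibble::as_tibble(as.data.frame(cnt)), ignore_attr = TRUE)
  expect_equal(screen_design(back), screen_design(cnt))
})
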