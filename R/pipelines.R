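#' End-to-end synthetic screen demonstration
#'
#' Generates a guide library with known gene effects, simulates a pooled
#' screen, writes the amplicon FASTQ, quantifies it back, scores the
#' screen, and writes all artifacts (library, truth, counts, gene table,
#' volcano table, a null-calibration report, and the resolved
#' configuration) into `dir`. All randomness derives from `seed` via
#' per-stage substreams, so a rerun with the same seed reproduces every
#' file byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Targeting genes in the synthetic library (default 150).
#' @param n_controls Non-targeting control guides (default 500).
#' @param n_hits Genes given a non-zero effect (default 20).
#' @param effect Effect size (log2) of hit genes (default -1.5).
#' @param screen Screen type (default `"proliferation"`).
#' @param n_replicates Replicates (default 4).
#' @param depth Reads per sample (default 1e5; FASTQ scale).
#' @param dispersion Read-noise dispersion (default 0.01).
#' @param n_perm Permutation pseudo-genes (default 2e4).
#' @param seed Root seed (default 1).
#' @return Invisibly, a list with the `screen_result`, the paths written,
#'   and the calibration summary.
#' @export
run_screen_demo <- function(dir, n_genes = 150, n_controls = 500,
                            n_hits = 20, effect = -1.5,
                            screen = "proliferation", n_replicates = 4,
                            depth = 1e5, dispersion = 0.01, n_perm = 2e4,
                            seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(n_genes = n_genes, n_controls = n_controls, n_hits = n_hits,
                 effect = effect, screen = screen,
                 n_replicates = n_replicates, depth = depth,
                 dispersion = dispersion, n_perm = n_perm, seed = seed)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))

  lib <- simulate_guide_library(n_genes, n_controls = n_controls,
                                seed = substream(seed, 1))
  hit_genes <- head(unique(lib$gene[lib$gene != CONTROL_LABEL]), n_hits)
  truth <- gene_effects(lib, setNames(rep(effect, n_hits), hit_genes))
  counts <- simulate_screen_counts(lib, truth, screen = screen,
                                   n_replicates = n_replicates, depth = depth,
                                   dispersion = dispersion,
                                   seed = substream(seed, 2))
  fastq <- file.path(dir, "reads.fastq")
  fq <- write_amplicon_fastq(counts, lib, fastq,
                             barcodes = sample_barcodes(
                               screen_design(counts)$sample,
                               seed = substream(seed, 3)),
                             error_rate = 0)
  quant <- suppressMessages(
    quantify_amplicons(fastq, lib, fq$barcodes,
                       design = screen_design(counts)))
  res <- score_screen(quant, lib, screen = screen, n_perm = n_perm,
                      seed = substream(seed, 4))

  null_genes <- res$genes[!res$genes$gene %in% hit_genes, ]
  ks <- suppressWarnings(ks.test(null_genes$p, "punif"))
  calibration <- list(
    n_null_genes = nrow(null_genes),
    ks_p_uniform = unname(ks$p.value),
    frac_null_q_below_0.05 = mean(null_genes$q < 0.05),
    n_hits_recovered = sum(res$genes$q[res$genes$gene %in% hit_genes] < 0.05),
    n_hits = n_hits)
  yaml::write_yaml(calibration, file.path(dir, "calibration.yaml"))

  write.table(as.data.frame(lib), file.path(dir, "library.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(truth), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_screen_counts(quant, file.path(dir, "counts.tsv"))
  write.table(as.data.frame(res$genes), file.path(dir, "gene_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  volcano <- mutate(res$genes, neg_log10_p = -log10(.data$p),
                    significant = .data$q < 0.05)
  write.table(as.data.frame(volcano), file.path(dir, "volcano.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(result = res, library = lib, truth = truth,
                 calibration = calibration, dir = dir))
}

#' End-to-end synthetic tracking demonstration
#'
#' Simulates two cell populations with different migratory persistence,
#' renders them as nuclei movies, re-detects and links the nuclei into
#' tracks, infers per-cell persistence and activity, and compares the two
#' populations with a Mann-Whitney U test. Writes the track table,
#' per-cell estimates, a truth-vs-estimate report, and the resolved
#' configuration into `dir`.
#'
#' @param dir Output directory.
#' @param n_cells Cells per population (default 12).
#' @param n_steps Velocity steps per track (default 60).
#' @param q Persistence of the two populations (default `c(0.2, 0.7)`).
#' @param a Activity of both populations, um/s (default 0.2).
#' @param dt Frame interval, s (default 60).
#' @param pixel_size um per pixel for rendering (default 2).
#' @param grid Inference grid (default a 100-point grid for speed).
#' @param seed Root seed (default 1).
#' @return Invisibly, a list with per-cell estimates, the comparison, and
#'   the paths written.
#' @export
run_tracking_demo <- function(dir, n_cells = 12, n_steps = 60,
                              q = c(0.2, 0.7), a = 0.2, dt = 60,
                              pixel_size = 2,
                              grid = hrw_grid(grid_size = 100), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(n_cells = n_cells, n_steps = n_steps, q = q, a = a, dt = dt,
                 pixel_size = pixel_size, grid_size = grid$grid_size,
                 p_min = grid$p_min, seed = seed)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))

  out_cells <- list(); out_comp <- list(); truth_rows <- list()
  est <- list()
  for (g in seq_along(q)) {
    tr <- simulate_tracks(n_cells, n_steps, q = q[g], a = a, dt = dt,
                          field_size = 60 * ceiling(sqrt(n_cells)),
                          seed = substream(seed, 10 + g))
    tr <- recenter_tracks(tr, margin = 40)
    movie <- render_nuclei_movie(tr, pixel_size = pixel_size,
                                 blob_sigma = 2, noise_sd = 0.02,
                                 path = file.path(dir, sprintf("movie_pop%d.tif", g)),
                                 seed = substream(seed, 20 + g))
    det <- detect_movie(movie, disk_radius = 12, min_area = 5)
    tracks <- build_tracks(det, pixel_size = pixel_size, dt = dt)
    fit <- infer_persistence(tracks, grid = grid)
    est[[g]] <- mutate(fit$cells, population = g, true_q = q[g], true_a = a)
  }
  cells <- bind_rows(est)
  comp <- compare_groups(cells$mean_q[cells$population == 1],
                         cells$mean_q[cells$population == 2])
  report <- cells |>
    group_by(.data$population) |>
    summarise(true_q = .data$true_q[1], mean_q = mean(.data$mean_q),
              true_a = .data$true_a[1], mean_a = mean(.data$mean_a),
              n_cells = n(), .groups = "drop")
  write.table(as.data.frame(cells), file.path(dir, "per_cell.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(report), file.path(dir, "truth_vs_estimate.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(mann_whitney_p = comp$p_value,
                        statistic = comp$statistic),
                   file.path(dir, "comparison.yaml"))
  invisible(list(cells = cells, comparison = comp, report = report,
                 dir = dir))
}

# Shift track positions so every coordinate is at least `margin` um from
# the origin (rendering requires in-frame positions).
recenter_tracks <- function(tracks, margin = 20) {
  for (ax in intersect(c("x", "y", "z"), names(tracks))) {
    tracks[[ax]] <- tracks[[ax]] - min(tracks[[ax]]) + margin
  }
  tracks
}
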