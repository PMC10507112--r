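#' Simulate guide counts for a pooled screen
#'
#' Generates a guide-by-sample count matrix with known ground truth. The
#' physical library is modelled with per-guide reference abundances drawn
#' once from a log-normal distribution (sd 1 in log2 units, the typical
#' skew of a plasmid library). Sequencing counts are drawn around
#' `depth * abundance` with Gamma-Poisson (negative binomial) read noise;
#' `dispersion = 0` gives an exact multinomial draw so column sums equal
#' `depth`.
#'
#' Two designs are supported:
#' \describe{
#'   \item{selection (`"proliferation"`, `"differentiation"`)}{per replicate,
#'     a `reference` and a `selected` sample; the selected expected abundance
#'     of a guide is `reference * 2^effect`.}
#'   \item{`"migration"`}{per replicate, a `reference` sample plus a
#'     `migratory` / `non_migratory` pair. Each guide's cells are split
#'     binomially between the pools; a gene effect shifts the log-odds of
#'     reaching the migratory pool by `effect * log(2)`, so for rare
#'     migration the migratory log2 fold-change approaches the effect.}
#' }
#'
#' @param library A `guide_library`.
#' @param effects An `effect_truth` table from [gene_effects()], or NULL for
#'   an all-null screen.
#' @param screen One of `"proliferation"`, `"differentiation"`, `"migration"`.
#' @param n_replicates Number of independent replicate experiments.
#' @param depth Sequencing reads per sample.
#' @param dispersion Negative-binomial dispersion of read noise (0 = pure
#'   multinomial sampling).
#' @param base_migration Baseline probability that a wild-type cell reaches
#'   the migratory pool (default 0.3, the scale of a 2 h transwell assay).
#' @param cells_per_guide Average cells per guide entering each migration
#'   replicate (default 500, the screen's coverage).
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `screen_counts`: `guide_id` plus one integer
#'   column per sample. The sample sheet is attached as attribute `design`
#'   (columns `sample`, `role`, `replicate`) and, for migration designs, the
#'   per-guide cell split as attribute `cells`.
#' @examples
#' lib <- simulate_guide_library(20, n_controls = 50, seed = 1)
#' cnt <- simulate_screen_counts(lib, depth = 1e4, seed = 2)
#' screen_design(cnt)
#' @export
simulate_screen_counts <- function(library, effects = NULL,
                                   screen = c("proliferation", "differentiation",
                                              "migration"),
                                   n_replicates = 4, depth = 1e6,
                                   dispersion = 0.01,
                                   base_migration = 0.3,
                                   cells_per_guide = 500,
                                   seed = NULL) {
  validate_guide_library(library)
  screen <- match.arg(screen)
  n_replicates <- check_positive_int(n_replicates, "n_replicates")
  depth <- check_number(depth, "depth", lower = 1)
  dispersion <- check_number(dispersion, "dispersion", lower = 0)
  base_migration <- check_number(base_migration, "base_migration", 1e-6, 1 - 1e-6)
  if (is.null(effects)) effects <- gene_effects(library)

  G <- nrow(library)
  eff <- guide_effect_vector(library, effects)

  with_seed(seed, {
    ref_abundance <- 2^rnorm(G, 0, 1)
    samples <- list()
    design <- list()
    cells <- list()
    for (r in seq_len(n_replicates)) {
      ref_name <- sprintf("reference_r%d", r)
      samples[[ref_name]] <- draw_reads(ref_abundance, depth, dispersion)
      design[[length(design) + 1L]] <- tibble(sample = ref_name,
                                              role = "reference", replicate = r)
      if (screen == "migration") {
        n_cells <- as.vector(rmultinom(1, round(cells_per_guide * G),
                                       ref_abundance / sum(ref_abundance)))
        p_mig <- stats::plogis(stats::qlogis(base_migration) + eff * log(2))
        n_mig <- rbinom(G, n_cells, p_mig)
        n_non <- n_cells - n_mig
        mig_name <- sprintf("migratory_r%d", r)
        non_name <- sprintf("non_migratory_r%d", r)
        samples[[mig_name]] <- draw_reads(n_mig, depth, dispersion)
        samples[[non_name]] <- draw_reads(n_non, depth, dispersion)
        design[[length(design) + 1L]] <- tibble(sample = mig_name,
                                                role = "migratory", replicate = r)
        design[[length(design) + 1L]] <- tibble(sample = non_name,
                                                role = "non_migratory",
                                                replicate = r)
        cells[[r]] <- tibble(guide_id = library$guide_id, replicate = r,
                             cells_total = n_cells, cells_migratory = n_mig,
                             cells_non_migratory = n_non)
      } else {
        sel_name <- sprintf("selected_r%d", r)
        samples[[sel_name]] <- draw_reads(ref_abundance * 2^eff, depth, dispersion)
        design[[length(design) + 1L]] <- tibble(sample = sel_name,
                                                role = "selected", replicate = r)
      }
    }
    out <- bind_cols(tibble(guide_id = library$guide_id), as_tibble(samples))
    attr(out, "design") <- bind_rows(design)
    attr(out, "screen") <- screen
    attr(out, "truth") <- effects
    if (screen == "migration") attr(out, "cells") <- bind_rows(cells)
    class(out) <- c("screen_counts", class(out))
    out
  })
}

# Per-guide effect vector: gene effect for targeting guides, 0 for controls.
guide_effect_vector <- function(library, effects) {
  eff <- setNames(effects$effect, effects$gene)
  out <- rep(0, nrow(library))
  targeting <- !is_control_guide(library)
  missing <- setdiff(unique(library$gene[targeting]), effects$gene)
  if (length(missing)) {
    abort(sprintf("`effects` is missing genes present in the library: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  out[targeting] <- eff[library$gene[targeting]]
  out
}

# Sequencing read counts for one sample around depth * abundance share.
# Gamma-Poisson gives negative-binomial marginals with the given dispersion;
# dispersion 0 collapses to an exact multinomial of size `depth`.
draw_reads <- function(abundance, depth, dispersion) {
  if (all(abundance == 0)) return(integer(length(abundance)))
  p <- abundance / sum(abundance)
  if (dispersion == 0) {
    as.vector(rmultinom(1, size = round(depth), prob = p))
  } else {
    mu <- depth * p * rgamma(length(p), shape = 1 / dispersion,
                             rate = 1 / dispersion)
    rpois(length(p), mu)
  }
}

#' Sample sheet of a count table
#'
#' @param counts A `screen_counts` tibble.
#' @return The design tibble (`sample`, `role`, `replicate`) attached to the
#'   counts.
#' @export
screen_design <- function(counts) {
  d <- attr(counts, "design")
  if (is.null(d)) abort("`counts` carries no design attribute.")
  d
}

#' Write / read a guide count table as TSV
#'
#' The design sheet is stored alongside as `<path>.design.tsv` so a round
#' trip preserves sample roles.
#'
#' @param counts A `screen_counts` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_counts <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(screen_design(counts)),
              paste0(path, ".design.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_counts
#' @export
read_screen_counts <- function(path) {
  out <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
  dpath <- paste0(path, ".design.tsv")
  if (file.exists(dpath)) {
    attr(out, "design") <- as_tibble(read.table(dpath, header = TRUE, sep = "\t",
                                                stringsAsFactors = FALSE))
  }
  class(out) <- c("screen_counts", class(out))
  out
}
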