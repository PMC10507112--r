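#' Simulate a pooled CRISPRi guide library
#'
#' Builds an index table for a pooled screen: `guides_per_gene` sgRNAs for
#' each of `n_genes` target genes plus `n_controls` non-targeting control
#' guides. The genome-wide library used in dHL-60 screens has this shape
#' (3 sgRNA per gene, ~500 non-targeting controls). Spacer sequences are
#' random unique 20-mers over ACGT.
#'
#' @param n_genes Number of target genes (>= 1).
#' @param guides_per_gene Guides per targeting gene (default 3).
#' @param n_controls Number of non-targeting control guides (default 500).
#' @param seed Optional integer seed; the same seed reproduces the table
#'   exactly.
#'
#' @return A tibble of class `guide_library` with columns `guide_id`,
#'   `sequence` (20-nt), and `gene` (gene symbol, or `"control"` for
#'   non-targeting guides).
#' @examples
#' lib <- simulate_guide_library(n_genes = 10, seed = 1)
#' table(lib$gene == "control")
#' @export
simulate_guide_library <- function(n_genes, guides_per_gene = 3, n_controls = 500,
                                   seed = NULL) {
  n_genes <- check_positive_int(n_genes, "n_genes")
  guides_per_gene <- check_positive_int(guides_per_gene, "guides_per_gene")
  n_controls <- check_positive_int(n_controls, "n_controls", min = 0L)

  n_guides <- n_genes * guides_per_gene + n_controls
  with_seed(seed, {
    sequences <- random_spacers(n_guides)
    genes <- c(rep(sprintf("GENE%05d", seq_len(n_genes)), each = guides_per_gene),
               rep(CONTROL_LABEL, n_controls))
    idx_in_gene <- c(rep(seq_len(guides_per_gene), times = n_genes),
                     seq_len(n_controls))
    guide_id <- ifelse(genes == CONTROL_LABEL,
                       sprintf("%s_%04d", CONTROL_LABEL, idx_in_gene),
                       sprintf("%s_sg%d", genes, idx_in_gene))
    out <- tibble(guide_id = guide_id, sequence = sequences, gene = genes)
    class(out) <- c("guide_library", class(out))
    out
  })
}

# Unique random 20-mers; collisions (p ~ n^2 / 4^20) are redrawn.
random_spacers <- function(n, width = 20L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  seqs <- draw(n)
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- draw(length(dup))
  }
  seqs
}

#' Validate a guide library table
#'
#' Checks the invariants a guide library must satisfy: unique guide ids,
#' 20-nt ACGT sequences, and a consistent per-gene guide count for all
#' targeting genes.
#'
#' @param library A `guide_library` tibble (or any data frame with
#'   `guide_id`, `sequence`, `gene` columns).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_guide_library <- function(library) {
  req <- c("guide_id", "sequence", "gene")
  if (!all(req %in% names(library))) {
    abort("`library` needs columns guide_id, sequence, gene.")
  }
  if (anyDuplicated(library$guide_id)) abort("guide_id values must be unique.")
  if (any(nchar(library$sequence) != 20L)) {
    abort("All guide sequences must be 20 nt.")
  }
  if (any(grepl("[^ACGT]", library$sequence))) {
    abort("Guide sequences may only contain A, C, G, T.")
  }
  counts <- table(library$gene[library$gene != CONTROL_LABEL])
  if (length(counts) > 1L && length(unique(as.integer(counts))) != 1L) {
    warn("Targeting genes do not all have the same number of guides.")
  }
  invisible(library)
}

is_control_guide <- function(library) library$gene == CONTROL_LABEL

#' Attach true gene effects to a library
#'
#' Builds the ground-truth effect table used by [simulate_screen_counts()].
#' Effects are per-gene selection log-ratios in log2 units: a gene with
#' effect -1 halves the expected abundance of its guides in the selected
#' population (or shifts the log-odds of reaching the migratory pool by
#' -1 log2 unit in migration designs). Control guides always carry effect 0.
#'
#' @param library A `guide_library`.
#' @param effects Named numeric vector of per-gene effects (log2 units);
#'   genes not named get effect 0.
#' @return A tibble of class `effect_truth` with columns `gene`, `effect`,
#'   and `class` (`"neutral"`, `"depleted"`, or `"enriched"`).
#' @examples
#' lib <- simulate_guide_library(5, seed = 1)
#' gene_effects(lib, c(GENE00001 = -1))
#' @export
gene_effects <- function(library, effects = NULL) {
  validate_guide_library(library)
  genes <- unique(library$gene[library$gene != CONTROL_LABEL])
  eff <- setNames(rep(0, length(genes)), genes)
  if (!is.null(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
      abort("`effects` must be a named numeric vector of gene effects.")
    }
    unknown <- setdiff(names(effects), genes)
    if (length(unknown)) {
      abort(sprintf("Unknown genes in `effects`: %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
    eff[names(effects)] <- effects
  }
  out <- tibble(
    gene = genes,
    effect = unname(eff),
    class = dplyr::case_when(
      eff < 0 ~ "depleted",
      eff > 0 ~ "enriched",
      TRUE ~ "neutral"
    )
  )
  class(out) <- c("effect_truth", class(out))
  out
}
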