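#' Score a pooled CRISPRi screen
#'
#' End-to-end gene scoring: per-measurement pseudocount log2 fold-changes
#' with median centering, optional unit-variance scaling, -1 flip of the
#' less-migratory population, averaging to one score per guide, gene
#' aggregation over guide triples, a permutation null from random control
#' triples, directional permutation p-values and Benjamini-Hochberg
#' adjustment.
#'
#' Measurement columns are derived from the sample sheet
#' ([screen_design()]): selection screens compare each replicate's
#' `selected` sample to its `reference`; migration screens contribute two
#' measurements per replicate (`migratory` vs reference, and the flipped
#' `non_migratory` vs reference). Unit-variance scaling is on for
#' differentiation and migration screens and off for proliferation, unless
#' overridden.
#'
#' @param counts A `screen_counts` tibble with a design attribute.
#' @param library The `guide_library`.
#' @param screen Screen type; defaults to the type recorded on `counts`.
#' @param pseudocount Pseudocount for [guide_lfc()] (default 32).
#' @param scale_unit_variance Override the per-screen scaling default.
#' @param n_perm Pseudo-genes in the permutation null (default 1e5).
#' @param two_sided Double directional p-values (default TRUE; see
#'   [permutation_p()]).
#' @param seed Optional integer seed (null construction).
#' @return An object of class `screen_result`: list with `genes` (tibble
#'   `gene`, `score`, `p`, `q`, `direction`, `n_guides`, `n_measurements`),
#'   `guide_scores`, `control_scores`, `null` (`perm_null`), and `params`.
#' @examples
#' lib <- simulate_guide_library(30, n_controls = 60, seed = 1)
#' cnt <- simulate_screen_counts(lib, depth = 5e4, n_replicates = 2, seed = 2)
#' res <- score_screen(cnt, lib, n_perm = 1000, seed = 3)
#' head(tidy(res))
#' @export
score_screen <- function(counts, library, screen = NULL, pseudocount = 32,
                         scale_unit_variance = NULL, n_perm = 1e5,
                         two_sided = TRUE, seed = NULL) {
  validate_guide_library(library)
  design <- screen_design(counts)
  screen <- screen %||% attr(counts, "screen") %||% "proliferation"
  screen <- match.arg(screen, c("proliferation", "differentiation", "migration"))
  if (is.null(scale_unit_variance)) {
    scale_unit_variance <- screen != "proliferation"
  }
  mm <- measurement_map(design, screen)
  lfc_cols <- list(guide_id = counts$guide_id)
  for (i in seq_len(nrow(mm))) {
    lfc_cols[[mm$name[i]]] <-
      guide_lfc(counts, mm$numerator[i], mm$reference[i],
                pseudocount = pseudocount)$lfc
  }
  lfc <- as_tibble(lfc_cols)
  guide_scores <- normalize_and_average(
    lfc, scale_unit_variance = scale_unit_variance,
    flip = mm$name[mm$flip])
  genes <- gene_score(guide_scores, library)
  ctrl <- control_scores(guide_scores, library)
  group_size <- as.integer(round(median(genes$n_guides)))
  null <- null_distribution(ctrl, group_size = group_size, n_groups = n_perm,
                            seed = seed)
  genes <- permutation_p(genes, null, two_sided = two_sided)
  genes <- mutate(genes, q = bh_adjust(.data$p),
                  n_measurements = nrow(mm))
  genes <- select(genes, "gene", "score", "p", "q", "direction",
                  "n_guides", "n_measurements")
  structure(list(genes = genes, guide_scores = guide_scores,
                 control_scores = ctrl, null = null, lfc = lfc,
                 params = list(screen = screen, pseudocount = pseudocount,
                               scale_unit_variance = scale_unit_variance,
                               n_perm = n_perm, two_sided = two_sided,
                               seed = seed)),
            class = "screen_result")
}

# One row per log2FC measurement column: numerator sample, reference
# sample, and whether the column is sign-flipped before averaging.
measurement_map <- function(design, screen) {
  refs <- design[design$role == "reference", ]
  if (!nrow(refs)) abort("Design has no reference sample.")
  out <- list()
  for (r in unique(design$replicate)) {
    ref <- refs$sample[refs$replicate == r]
    if (!length(ref)) abort(sprintf("Replicate %s has no reference sample.", r))
    others <- design[design$replicate == r & design$role != "reference", ]
    for (i in seq_len(nrow(others))) {
      role <- others$role[i]
      out[[length(out) + 1L]] <- tibble(
        name = sprintf("%s_r%s", role, r),
        numerator = others$sample[i],
        reference = ref[1],
        flip = role == "non_migratory")
    }
  }
  if (!length(out)) abort("Design has no selected/migratory samples.")
  bind_rows(out)
}

#' @export
print.screen_result <- function(x, ...) {
  g <- x$genes
  cat(sprintf("<screen_result> %s screen: %d genes, %d measurements, %d controls\n",
              x$params$screen, nrow(g), g$n_measurements[1],
              length(x$control_scores)))
  cat(sprintf("  significant at q < 0.05: %d\n", sum(g$q < 0.05)))
  invisible(x)
}

#' Compare two scored screens
#'
#' Correlation of gene-level scores over the shared gene universe plus the
#' overlap of significant gene sets at a q threshold (the basis of
#' cross-screen concordance statements such as the chemotaxis vs
#' chemokinesis rho = 0.99).
#'
#' @param a,b `screen_result` objects.
#' @param q_threshold Significance cutoff on BH-adjusted q (default 0.05).
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @return A list with `correlation`, `n_shared`, `significant_a/b`,
#'   and `overlap` (tibble: both / a_only / b_only / neither counts).
#' @export
compare_screens <- function(a, b, q_threshold = 0.05, method = "pearson") {
  ga <- a$genes; gb <- b$genes
  shared <- intersect(ga$gene, gb$gene)
  if (!length(shared)) abort("No shared genes between the two screens.")
  sa <- ga[match(shared, ga$gene), ]
  sb <- gb[match(shared, gb$gene), ]
  siga <- shared[sa$q < q_threshold]
  sigb <- shared[sb$q < q_threshold]
  overlap <- tibble(
    set = c("both", "a_only", "b_only", "neither"),
    n_genes = c(length(intersect(siga, sigb)),
                length(setdiff(siga, sigb)),
                length(setdiff(sigb, siga)),
                length(shared) - length(union(siga, sigb))))
  list(correlation = cor(sa$score, sb$score, method = method),
       n_shared = length(shared),
       significant_a = length(siga), significant_b = length(sigb),
       overlap = overlap)
}

#' Significant-set intersections across screens
#'
#' Counts genes in every intersection pattern of the significant sets of
#' several screens (the UpSet-style overlap summary).
#'
#' @param results Named list of `screen_result` objects.
#' @param q_threshold Significance cutoff (default 0.05).
#' @return A tibble with one row per observed membership pattern: one
#'   logical column per screen plus `n_genes`.
#' @export
screen_overlap <- function(results, q_threshold = 0.05) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    abort("`results` must be a named list.")
  }
  sets <- purrr::map(results, ~ .x$genes$gene[.x$genes$q < q_threshold])
  universe <- unique(unlist(purrr::map(results, ~ .x$genes$gene)))
  member <- purrr::map(sets, ~ universe %in% .x)
  tab <- as_tibble(member)
  tab |>
    group_by(across(dplyr::everything())) |>
    summarise(n_genes = n(), .groups = "drop") |>
    filter(dplyr::if_any(-"n_genes", identity))
}

#' Transwell migration fraction
#'
#' Fraction of cells recovered in the migratory compartment:
#' `n_migratory / (n_migratory + n_remaining)`.
#'
#' @param n_migratory,n_remaining Non-negative cell counts (vectorised).
#' @return Numeric fraction(s) in `[0, 1]`.
#' @examples
#' migration_fraction(30, 70)  # 0.30
#' @export
migration_fraction <- function(n_migratory, n_remaining) {
  if (any(n_migratory < 0) || any(n_remaining < 0)) {
    abort("Counts must be non-negative.")
  }
  total <- n_migratory + n_remaining
  if (any(total == 0)) {
    abort("Migration fraction undefined: both counts are zero.")
  }
  n_migratory / total
}
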