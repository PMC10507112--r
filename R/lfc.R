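#' Per-guide log2 fold-change with pseudocount
#'
#' Computes `log2(selected + pc) - log2(reference + pc)` per guide. The
#' pseudocount (default 32) keeps fold-changes finite and damps erroneously
#' large values for guides with low library representation. Median centering
#' subtracts the median over all guides, which simultaneously implements
#' the per-replicate median normalization and absorbs sequencing-depth
#' differences between the two samples.
#'
#' @param counts A `screen_counts` tibble (or any tibble with `guide_id`
#'   and count columns).
#' @param selected,reference Column names of the selected and reference
#'   samples.
#' @param pseudocount Pseudocount added to every raw count (default 32).
#' @param median_center Subtract the across-guide median (default TRUE).
#' @return A tibble `guide_id`, `lfc`.
#' @examples
#' x <- tibble::tibble(guide_id = "g1", sel = 96L, ref = 32L)
#' guide_lfc(x, "sel", "ref", median_center = FALSE)$lfc  # log2(128/64) = 1
#' @export
guide_lfc <- function(counts, selected, reference, pseudocount = 32,
                      median_center = TRUE) {
  pseudocount <- check_number(pseudocount, "pseudocount", lower = 0)
  for (col in c(selected, reference)) {
    if (!col %in% names(counts)) abort(sprintf("No column `%s` in counts.", col))
    if (any(counts[[col]] < 0)) abort(sprintf("Negative counts in `%s`.", col))
  }
  lfc <- log2(counts[[selected]] + pseudocount) -
    log2(counts[[reference]] + pseudocount)
  if (median_center) lfc <- lfc - median(lfc)
  tibble(guide_id = counts$guide_id, lfc = lfc)
}

#' Normalize and average fold-change measurements
#'
#' Collapses a guide-by-measurement log2 fold-change matrix to one score
#' per guide. Columns flagged in `flip` (the less-migratory population of a
#' dual-collection migration assay) are multiplied by -1 so both
#' populations report the same sign; with `scale_unit_variance` each column
#' is divided by its standard deviation before averaging (used for the
#' differentiation and migration screens, not for proliferation). The
#' result is the unweighted mean across measurement columns.
#'
#' @param lfc A tibble with `guide_id` plus one numeric column per
#'   measurement (replicate x population).
#' @param scale_unit_variance Scale each column to unit variance first?
#' @param flip Character vector of column names (or logical per measurement
#'   column) to negate before scaling.
#' @return A tibble `guide_id`, `score`.
#' @export
normalize_and_average <- function(lfc, scale_unit_variance = FALSE,
                                  flip = NULL) {
  meas <- setdiff(names(lfc), "guide_id")
  if (!length(meas)) abort("`lfc` has no measurement columns.")
  m <- as.matrix(lfc[meas])
  if (!all(is.finite(m))) abort("Non-finite fold-change values.")
  if (is.logical(flip)) {
    if (length(flip) != length(meas)) {
      abort("Logical `flip` must have one entry per measurement column.")
    }
    flip <- meas[flip]
  }
  if (length(flip)) {
    if (!all(flip %in% meas)) abort("`flip` names unknown columns.")
    m[, flip] <- -m[, flip]
  }
  if (scale_unit_variance) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("Zero-variance measurement column(s): %s",
                    paste(meas[sds == 0], collapse = ", ")))
    }
    m <- sweep(m, 2, sds, "/")
  }
  tibble(guide_id = lfc$guide_id, score = rowMeans(m))
}

#' Aggregate guide scores to gene scores
#'
#' Unweighted mean of the averaged guide scores over each gene's guides.
#' Control guides are excluded from the gene table (they feed the
#' permutation null instead, see [null_distribution()]).
#'
#' @param guide_scores A tibble `guide_id`, `score` (from
#'   [normalize_and_average()]).
#' @param library The `guide_library`.
#' @return A tibble `gene`, `score`, `n_guides`, sorted by gene.
#' @export
gene_score <- function(guide_scores, library) {
  validate_guide_library(library)
  joined <- left_join(guide_scores, library[c("guide_id", "gene")],
                      by = "guide_id")
  if (anyNA(joined$gene)) {
    abort("Some guide_ids are absent from the library.")
  }
  joined |>
    filter(.data$gene != CONTROL_LABEL) |>
    group_by(.data$gene) |>
    summarise(score = mean(.data$score), n_guides = n(), .groups = "drop") |>
    arrange(.data$gene)
}

#' Control-guide scores
#'
#' @param guide_scores A tibble `guide_id`, `score`.
#' @param library The `guide_library`.
#' @return Numeric vector of averaged scores of the non-targeting control
#'   guides.
#' @export
control_scores <- function(guide_scores, library) {
  ids <- library$guide_id[is_control_guide(library)]
  out <- guide_scores$score[match(ids, guide_scores$guide_id)]
  if (anyNA(out)) abort("Control guides missing from `guide_scores`.")
  out
}
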