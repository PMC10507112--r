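#' Permutation null from control-guide triples
#'
#' Builds the empirical null distribution of gene scores by averaging
#' random groups of `group_size` non-targeting control guides — pseudo-genes
#' with the same construction as real gene scores (the screens use triples,
#' matching 3 sgRNA per gene). Guides are sampled without replacement
#' within a group; groups are drawn independently.
#'
#' @param control_scores Numeric vector of averaged control-guide scores
#'   (~500 in the genome-wide library).
#' @param group_size Guides per pseudo-gene (default 3).
#' @param n_groups Number of pseudo-genes to draw (default 1e5, giving p
#'   resolution ~1e-5).
#' @param seed Optional integer seed.
#' @return An object of class `perm_null`: list with `scores` (length
#'   `n_groups`), `group_size`, `n_groups`, `seed`.
#' @export
null_distribution <- function(control_scores, group_size = 3, n_groups = 1e5,
                              seed = NULL) {
  group_size <- check_positive_int(group_size, "group_size")
  n_groups <- check_positive_int(n_groups, "n_groups")
  nc <- length(control_scores)
  if (nc < group_size) {
    abort(sprintf("Need at least %d control scores, got %d.", group_size, nc))
  }
  if (any(!is.finite(control_scores))) abort("Non-finite control scores.")
  with_seed(seed, {
    # joint draw with rejection of within-group duplicates: exact
    # without-replacement sampling, vectorised over all groups
    idx <- matrix(sample.int(nc, group_size * n_groups, replace = TRUE),
                  nrow = group_size)
    if (group_size > 1L) {
      bad <- which(apply_dup(idx))
      while (length(bad)) {
        idx[, bad] <- sample.int(nc, group_size * length(bad), replace = TRUE)
        bad <- bad[apply_dup(idx[, bad, drop = FALSE])]
      }
    }
    scores <- colMeans(matrix(control_scores[idx], nrow = group_size))
    structure(list(scores = scores, group_size = group_size,
                   n_groups = n_groups, seed = seed),
              class = "perm_null")
  })
}

apply_dup <- function(m) {
  if (nrow(m) == 2L) m[1, ] == m[2, ]
  else apply(m, 2, anyDuplicated) > 0L
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null> %d pseudo-genes of %d control guides (mean %.4f, sd %.4f)\n",
    x$n_groups, x$group_size, mean(x$scores), sd(x$scores)))
  invisible(x)
}

#' Permutation p-values against a control null
#'
#' For each gene, the test direction is taken from the sign of the observed
#' score relative to the null median, and the directional p-value is
#' `(1 + #{null at least as extreme in that direction}) / (1 + n_groups)`
#' (the add-one correction keeps p in `(0, 1]`). By default the directional
#' p is doubled (capped at 1), which makes null p-values uniform and keeps
#' the Benjamini-Hochberg step calibrated; `two_sided = FALSE` returns the
#' raw directional p.
#'
#' @param genes A gene-score tibble (`gene`, `score`) from [gene_score()],
#'   or a bare numeric vector of scores.
#' @param null A `perm_null` from [null_distribution()].
#' @param two_sided Double the directional p-value (default TRUE).
#' @return The input tibble with `p` and `direction` (+1/-1) columns (or a
#'   tibble `score`, `p`, `direction` for vector input).
#' @export
permutation_p <- function(genes, null, two_sided = TRUE) {
  if (!inherits(null, "perm_null")) abort("`null` must be a perm_null object.")
  if (is.numeric(genes)) genes <- tibble(score = genes)
  if (!"score" %in% names(genes)) abort("`genes` needs a `score` column.")
  ns <- sort(null$scores)
  n <- length(ns)
  med <- median(ns)
  s <- genes$score
  n_ge <- n - findInterval(s, ns, left.open = TRUE)  # #{null >= s}
  n_le <- findInterval(s, ns)                        # #{null <= s}
  up <- s >= med
  p <- ifelse(up, (1 + n_ge) / (1 + n), (1 + n_le) / (1 + n))
  if (two_sided) p <- pmin(1, 2 * p)
  mutate(genes, p = p, direction = ifelse(up, 1L, -1L))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input validation;
#' monotonicity (q >= p elementwise, non-decreasing in rank) is inherent to
#' the procedure.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Vector of adjusted q-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must be numeric in (0, 1].")
  }
  p.adjust(p, method = "BH")
}
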