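#' Tidy a scored screen
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return The per-gene tibble (`gene`, `score`, `p`, `q`, `direction`,
#'   `n_guides`, `n_measurements`).
#' @export
tidy.screen_result <- function(x, ...) x$genes

#' One-row summary of a scored screen
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return A one-row tibble: screen type, gene/control counts, number of
#'   significant genes at q < 0.05 (split by direction), permutations.
#' @export
glance.screen_result <- function(x, ...) {
  g <- x$genes
  tibble(screen = x$params$screen,
         n_genes = nrow(g),
         n_controls = length(x$control_scores),
         n_measurements = g$n_measurements[1],
         n_significant = sum(g$q < 0.05),
         n_depleted = sum(g$q < 0.05 & g$direction < 0),
         n_enriched = sum(g$q < 0.05 & g$direction > 0),
         n_perm = x$null$n_groups)
}

#' Tidy a persistence fit
#'
#' @param x A `persistence_fit`.
#' @param ... Unused.
#' @return The per-cell tibble (`cell`, `mean_q`, `mean_a`, `n_steps`).
#' @export
tidy.persistence_fit <- function(x, ...) x$cells

#' One-row summary of a persistence fit
#'
#' @param x A `persistence_fit`.
#' @param ... Unused.
#' @return A one-row tibble with cell count and population means.
#' @export
glance.persistence_fit <- function(x, ...) {
  tibble(n_cells = nrow(x$cells),
         mean_q = mean(x$cells$mean_q),
         mean_a = mean(x$cells$mean_a),
         grid_size = x$grid$grid_size,
         p_min = x$grid$p_min)
}

#' Tidy a differentiation axis
#'
#' @param x A `diff_axis`.
#' @param ... Unused.
#' @return A tibble with one row per channel: `channel`, `loading`,
#'   `center`.
#' @export
tidy.diff_axis <- function(x, ...) {
  tibble(channel = x$channels, loading = unname(x$loadings),
         center = unname(x$center))
}

#' One-row summary of a differentiation axis
#'
#' @param x A `diff_axis`.
#' @param ... Unused.
#' @return A one-row tibble: variance explained, component sds, event
#'   count.
#' @export
glance.diff_axis <- function(x, ...) {
  tibble(var_explained = x$var_explained,
         sdev1 = x$sdev[1], sdev2 = x$sdev[2],
         n_events = length(x$projections))
}
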