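#' Log-likelihood of one random-walk step
#'
#' Log density of `v_next` given `v_prev` under the heterogeneous random
#' walk `v_next = q * v_prev + a * xi` with isotropic standard Gaussian
#' noise `xi`: a product of per-axis normal densities with mean
#' `q * v_prev` and standard deviation `a`.
#'
#' @param v_next,v_prev Numeric velocity vectors (2 or 3 components, same
#'   units as `a`).
#' @param q Persistence in `[-1, 1]`.
#' @param a Activity (noise amplitude) in the same units as the
#'   velocities; `a = 0` yields `-Inf` unless `v_next == q * v_prev`
#'   exactly.
#' @return The log density (a single number).
#' @examples
#' hrw_loglik(c(0.1, 0), c(0.2, 0), q = 0.5, a = 0.1)
#' @export
hrw_loglik <- function(v_next, v_prev, q, a) {
  if (length(v_next) != length(v_prev)) {
    abort("`v_next` and `v_prev` must have equal length.")
  }
  d <- length(v_next)
  if (!d %in% c(2L, 3L)) abort("Velocities must have 2 or 3 components.")
  q <- check_number(q, "q", -1, 1)
  a <- check_number(a, "a", lower = 0)
  resid <- v_next - q * v_prev
  if (a == 0) {
    return(if (all(resid == 0)) Inf else -Inf)
  }
  sum(dnorm(resid, mean = 0, sd = a, log = TRUE))
}

#' Inference grid for persistence and activity
#'
#' The discrete grid on which the sequential filter operates: `grid_size`
#' persistence values spanning `[-1, 1]` and `grid_size` activity values
#' spanning `(0, a_max]` um/s. The defaults are the empirically chosen
#' inference parameters for dHL-60 nuclei tracks: grid size 200, jump
#' floor `p_min = 1e-5`, box kernel radii 2 for both axes, activities up
#' to 0.5 um/s.
#'
#' @param grid_size Grid points per axis (default 200).
#' @param a_max Largest activity on the grid, um/s (default 0.5).
#' @param p_min Probability floor mixed in each propagation step, allowing
#'   parameter jumps (default 1e-5).
#' @param kernel_radius Box kernel radii in grid cells, `c(q, a)`
#'   (default `c(2, 2)`).
#' @return A list of class `hrw_grid`.
#' @export
hrw_grid <- function(grid_size = 200, a_max = 0.5, p_min = 1e-5,
                     kernel_radius = c(2, 2)) {
  grid_size <- check_positive_int(grid_size, "grid_size", min = 3L)
  a_max <- check_number(a_max, "a_max", lower = 1e-12)
  p_min <- check_number(p_min, "p_min", lower = 1e-300, upper = 1)
  if (length(kernel_radius) == 1L) kernel_radius <- rep(kernel_radius, 2L)
  structure(list(
    q = seq(-1, 1, length.out = grid_size),
    a = seq(a_max / grid_size, a_max, length.out = grid_size),
    grid_size = grid_size, a_max = a_max, p_min = p_min,
    r_q = as.integer(kernel_radius[1]), r_a = as.integer(kernel_radius[2])),
    class = "hrw_grid")
}

#' Infer time-varying persistence and activity
#'
#' Sequential Bayesian inference on a discrete (persistence, activity)
#' grid, one cell at a time. The filter starts from a uniform prior,
#' multiplies in each step's likelihood and renormalizes (per-step
#' estimates are the posterior means at this point), then propagates the
#' posterior by a truncated box kernel and mixes in the uniform
#' distribution at weight `p_min` so the tracked parameters may jump.
#'
#' @param tracks A `track_set` (um positions; `dt` attribute in seconds),
#'   or a tibble of velocities `cell`, `step`, `vx`, `vy` (and `vz`) in
#'   um/s.
#' @param grid An [hrw_grid()].
#' @param use_z Include z velocities of 3D tracks (default TRUE).
#' @return An object of class `persistence_fit`: list with `cells`
#'   (tibble `cell`, `mean_q`, `mean_a`, `n_steps`), `steps` (tibble
#'   `cell`, `step`, `q_hat`, `a_hat`), and `grid`.
#' @examples
#' tr <- simulate_tracks(2, 100, q = 0.6, a = 0.2, seed = 1)
#' fit <- infer_persistence(tr, hrw_grid(grid_size = 50))
#' tidy(fit)
#' @export
infer_persistence <- function(tracks, grid = hrw_grid(), use_z = TRUE) {
  if (!inherits(grid, "hrw_grid")) abort("`grid` must come from hrw_grid().")
  v <- if (all(c("vx", "vy") %in% names(tracks))) {
    tracks
  } else {
    track_velocities(tracks)
  }
  vcols <- intersect(c("vx", "vy", "vz"), names(v))
  if (!use_z) vcols <- setdiff(vcols, "vz")
  if (any(!is.finite(as.matrix(v[vcols])))) {
    abort("Non-finite velocities.")
  }
  cells <- unique(v$cell)
  step_rows <- vector("list", length(cells))
  cell_rows <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    vi <- as.matrix(v[v$cell == cells[k], vcols, drop = FALSE])
    if (nrow(vi) < 2L) {
      abort(sprintf("Cell %s has fewer than 2 velocity samples.", cells[k]))
    }
    fit <- hrw_filter_cpp(vi, grid$q, grid$a, grid$p_min, grid$r_q, grid$r_a)
    step_rows[[k]] <- tibble(cell = cells[k],
                             step = seq_along(fit$q_hat),
                             q_hat = fit$q_hat, a_hat = fit$a_hat)
    cell_rows[[k]] <- tibble(cell = cells[k],
                             mean_q = mean(fit$q_hat),
                             mean_a = mean(fit$a_hat),
                             n_steps = nrow(vi))
  }
  structure(list(cells = bind_rows(cell_rows), steps = bind_rows(step_rows),
                 grid = grid),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf(
    "<persistence_fit> %d cells (grid %d, p_min %g, kernel radii %d/%d)\n",
    nrow(x$cells), x$grid$grid_size, x$grid$p_min, x$grid$r_q, x$grid$r_a))
  cat(sprintf("  mean persistence %.3f, mean activity %.3f um/s\n",
              mean(x$cells$mean_q), mean(x$cells$mean_a)))
  invisible(x)
}

#' Summarise persistence estimates, optionally by group
#'
#' Per-cell posterior-mean persistence and activity; with a grouping
#' vector (e.g. field of view or cell line), per-group means are added and
#' two-group comparisons can be run with [compare_groups()].
#'
#' @param fit A `persistence_fit`.
#' @param group Optional vector (length = number of cells, aligned with
#'   `fit$cells`) of group labels.
#' @return A tibble of per-cell summaries (with `group` column if given);
#'   per-group means are attached as attribute `group_means`.
#' @export
summarize_persistence <- function(fit, group = NULL) {
  out <- fit$cells
  if (!is.null(group)) {
    if (length(group) != nrow(out)) {
      abort("`group` must have one entry per cell.")
    }
    out$group <- group
    attr(out, "group_means") <- out |>
      group_by(.data$group) |>
      summarise(mean_q = mean(.data$mean_q), mean_a = mean(.data$mean_a),
                n_cells = n(), .groups = "drop")
  }
  out
}
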