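#' Simulate heterogeneous persistent random walk tracks
#'
#' Cells move by the velocity process `v[t+1] = q[t] * v[t] + a[t] * xi[t]`
#' with isotropic standard Gaussian noise `xi` per axis: persistence `q`
#' (in `[-1, 1]`; 0 is diffusive, negative is reversive) couples successive
#' velocities, and activity `a` sets the speed scale. Activities are given
#' in um/s and converted internally to um per frame via `dt`; positions are
#' cumulative sums of per-frame velocities. Initial velocities are drawn
#' from the stationary distribution (per-axis sd `a*dt/sqrt(1-q^2)`), so
#' constant-parameter tracks are stationary from the first step.
#'
#' @param n_cells Number of cells.
#' @param n_steps Number of velocity steps per cell (>= 2); tracks have
#'   `n_steps + 1` positions.
#' @param q Persistence: scalar, per-cell vector, or `n_cells x n_steps`
#'   schedule matrix.
#' @param a Activity in um/s: scalar, per-cell vector, or schedule matrix.
#' @param dt Frame interval in seconds (default 60, the collagen ECM
#'   acquisition rate).
#' @param dims 2 or 3 spatial dimensions.
#' @param field_size Cells start on a jittered grid inside a square (or
#'   cube) of this side length, in um (default 60 um spacing per cell).
#' @param seed Optional integer seed.
#' @return A tibble of class `track_set` with columns `cell`, `t` (frame),
#'   `x`, `y` (and `z`) in um, plus attributes `dt` (s), `pixel_size`
#'   (NA, positions are metric), and `truth` (per-cell per-step `q` and
#'   `a_ums`).
#' @examples
#' tr <- simulate_tracks(5, 50, q = 0.5, a = 0.2, seed = 1)
#' head(tr)
#' @export
simulate_tracks <- function(n_cells, n_steps, q = 0, a = 0.2, dt = 60,
                            dims = 2, field_size = NULL, seed = NULL) {
  n_cells <- check_positive_int(n_cells, "n_cells")
  n_steps <- check_positive_int(n_steps, "n_steps", min = 2L)
  dt <- check_number(dt, "dt", lower = 1e-9)
  if (!dims %in% c(2, 3)) abort("`dims` must be 2 or 3.")
  qm <- schedule_matrix(q, n_cells, n_steps, "q")
  am <- schedule_matrix(a, n_cells, n_steps, "a")
  if (any(abs(qm) > 1)) abort("Persistence values must lie in [-1, 1].")
  if (any(am < 0)) abort("Activities must be non-negative.")
  if (is.null(field_size)) field_size <- 60 * ceiling(sqrt(n_cells))

  with_seed(seed, {
    origins <- grid_origins(n_cells, field_size, dims)
    axes <- c("x", "y", "z")[seq_len(dims)]
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      a_step <- am[i, ] * dt                       # um per frame
      v <- matrix(0, n_steps, dims)
      sd0 <- a_step[1] / sqrt(max(1 - qm[i, 1]^2, 1e-12))
      v[1, ] <- rnorm(dims, 0, sd0)
      noise <- matrix(rnorm(n_steps * dims), n_steps, dims)
      for (t in 2:n_steps) {
        v[t, ] <- qm[i, t] * v[t - 1, ] + a_step[t] * noise[t, ]
      }
      pos <- rbind(origins[i, ],
                   sweep(apply(v, 2, cumsum), 2, origins[i, ], "+"))
      rows[[i]] <- bind_cols(
        tibble(cell = i, t = 0:n_steps),
        as_tibble(setNames(as.data.frame(pos), axes)))
    }
    out <- bind_rows(rows)
    attr(out, "dt") <- dt
    attr(out, "pixel_size") <- NA_real_
    attr(out, "truth") <- tibble(
      cell = rep(seq_len(n_cells), each = n_steps),
      step = rep(seq_len(n_steps), n_cells),
      q = as.vector(t(qm)), a_ums = as.vector(t(am)))
    class(out) <- c("track_set", class(out))
    out
  })
}

schedule_matrix <- function(x, n_cells, n_steps, name) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(n_cells, n_steps))) {
      abort(sprintf("`%s` schedule must be n_cells x n_steps.", name))
    }
    return(x)
  }
  if (length(x) == 1L) return(matrix(x, n_cells, n_steps))
  if (length(x) == n_cells) return(matrix(x, n_cells, n_steps))
  if (length(x) == n_steps) return(matrix(x, n_cells, n_steps, byrow = TRUE))
  abort(sprintf("`%s` must be scalar, per-cell, per-step, or a matrix.", name))
}

grid_origins <- function(n_cells, field_size, dims) {
  side <- ceiling(n_cells^(1 / dims))
  spacing <- field_size / side
  g <- (seq_len(side) - 0.5) * spacing
  pts <- as.matrix(expand.grid(rep(list(g), dims)))[seq_len(n_cells), ,
                                                    drop = FALSE]
  pts + matrix(runif(n_cells * dims, -spacing / 10, spacing / 10),
               n_cells, dims)
}

#' Per-step velocities of a track set
#'
#' Non-overlapping step velocities `(pos[t+1] - pos[t]) / dt` in um/s.
#'
#' @param tracks A `track_set` tibble.
#' @param dt Frame interval in seconds; defaults to the track set's.
#' @return A tibble `cell`, `step`, `vx`, `vy` (and `vz`).
#' @export
track_velocities <- function(tracks, dt = NULL) {
  dt <- dt %||% attr(tracks, "dt") %||% 1
  axes <- intersect(c("x", "y", "z"), names(tracks))
  tracks |>
    group_by(.data$cell) |>
    arrange(.data$t, .by_group = TRUE) |>
    summarise(step = list(seq_len(n() - 1L)),
              across(dplyr::all_of(axes), ~ list(diff(.x) / dt)),
              .groups = "drop") |>
    tidyr::unnest(cols = dplyr::all_of(c("step", axes))) |>
    rename(vx = "x", vy = "y", dplyr::any_of(c(vz = "z")))
}

#' Ensemble mean squared displacement
#'
#' MSD over time lags, averaged over all cells and start frames. For a
#' memoryless walk (q = 0) the MSD grows linearly with lag.
#'
#' @param tracks A `track_set`.
#' @param max_lag Largest lag, in frames (default a quarter of the track).
#' @return A tibble `lag_frames`, `lag_s`, `msd` (um^2) with the R^2 of a
#'   linear fit through the origin region attached as attribute
#'   `linear_r2`.
#' @export
track_msd <- function(tracks, max_lag = NULL) {
  dt <- attr(tracks, "dt") %||% 1
  axes <- intersect(c("x", "y", "z"), names(tracks))
  split_cells <- split(tracks[axes], tracks$cell)
  n_frames <- min(vapply(split_cells, nrow, 0L))
  max_lag <- max_lag %||% max(2L, n_frames %/% 4L)
  lags <- seq_len(min(max_lag, n_frames - 1L))
  msd <- vapply(lags, function(L) {
    mean(unlist(purrr::map(split_cells, function(m) {
      mm <- as.matrix(m)
      d <- mm[-seq_len(L), , drop = FALSE] -
        mm[seq_len(nrow(mm) - L), , drop = FALSE]
      rowSums(d^2)
    })))
  }, 0)
  out <- tibble(lag_frames = lags, lag_s = lags * dt, msd = msd)
  fit <- lm(msd ~ lag_frames, data = out)
  attr(out, "linear_r2") <- summary(fit)$r.squared
  out
}
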