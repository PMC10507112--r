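#' Simulate bivariate flow-cytometry populations
#'
#' Events are drawn from a bivariate Gaussian in log10-fluorescence space
#' (two surface-marker channels), optionally shifted by `shift` along a
#' stated unit axis — the co-induction structure of differentiation
#' markers such as CD11b (ITGAM) and FPR1.
#'
#' @param n_cells Number of events.
#' @param mean Length-2 channel means (log10 units).
#' @param cov 2x2 symmetric positive-definite covariance.
#' @param shift Displacement along `axis` (log10 units, default 0).
#' @param axis Unit 2-vector of the shift direction (normalised
#'   internally; default the diagonal).
#' @param channels Channel names.
#' @param seed Optional integer seed.
#' @return A tibble of class `flow_sample` with one column per channel;
#'   ground truth (`axis`, `shift`) attached as attribute `truth`.
#' @export
simulate_flow <- function(n_cells, mean = c(2, 2), cov = diag(0.04, 2),
                          shift = 0, axis = c(1, 1), channels = c("ch1", "ch2"),
                          seed = NULL) {
  n_cells <- check_positive_int(n_cells, "n_cells")
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))) || any(eigen(cov)$values <= 0)) {
    abort("`cov` must be symmetric positive-definite.")
  }
  u <- axis / sqrt(sum(axis^2))
  with_seed(seed, {
    ev <- MASS::mvrnorm(n_cells, mu = mean + shift * u, Sigma = cov)
    out <- as_tibble(setNames(as.data.frame(ev), channels))
    attr(out, "truth") <- list(axis = u, shift = shift, mean = mean,
                               cov = cov)
    class(out) <- c("flow_sample", class(out))
    out
  })
}

#' Gate events on two scatter/fluorescence channels
#'
#' Retains events strictly inside a polygon (or ellipse) gate — the
#' forward/side-scatter gate isolating the live-cell population.
#'
#' @param events A tibble of events.
#' @param gate Either a two-column matrix / data frame of polygon vertices,
#'   or a list `list(center =, shape =, radius =)` defining the ellipse
#'   `(x - center)' shape^{-1} (x - center) < radius^2`.
#' @param channels The two columns gated on (default the first two).
#' @return The gated events; the retained fraction is reported and
#'   attached as attribute `retained_fraction`.
#' @export
gate_events <- function(events, gate, channels = names(events)[1:2]) {
  x <- as.matrix(events[channels])
  if (is.list(gate) && !is.data.frame(gate)) {
    if (!all(c("center", "shape", "radius") %in% names(gate))) {
      abort("Ellipse gate needs `center`, `shape`, `radius`.")
    }
    if (gate$radius <= 0 || det(as.matrix(gate$shape)) <= 0) {
      abort("Degenerate ellipse gate.")
    }
    md <- stats::mahalanobis(x, gate$center, as.matrix(gate$shape))
    inside <- md < gate$radius^2
  } else {
    poly <- as.matrix(gate)
    if (nrow(poly) < 3L || polygon_area(poly) == 0) {
      abort("Degenerate polygon gate (fewer than 3 vertices or zero area).")
    }
    inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), x)
  }
  out <- events[inside, ]
  frac <- if (nrow(events)) mean(inside) else 1
  inform(sprintf("gate_events: retained %d/%d events (%.1f%%)",
                 sum(inside), nrow(events), 100 * frac))
  if (!nrow(out)) warn("Gate retained no events.")
  attr(out, "retained_fraction") <- frac
  out
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Differentiation (co-induction) axis by pooled PCA
#'
#' The leading eigenvector of the 2x2 covariance of pooled log-fluorescence
#' events defines the marker co-induction axis; projections are centered
#' data times the loadings. The axis sign is fixed so both loadings are
#' non-negative when possible (differentiated, high/high cells project
#' positive). With exactly equal eigenvalues the tie is broken toward the
#' diagonal `(1, 1)/sqrt(2)` with a warning.
#'
#' @param events A tibble of pooled events (rows from every sample being
#'   compared, so all lines share one axis).
#' @param channels The two channels to use (default the first two).
#' @return An object of class `diff_axis`: list with `loadings` (unit
#'   2-vector), `center`, `sdev` (component standard deviations),
#'   `var_explained`, `projections` (per-event scores), and the pooled
#'   `events`.
#' @export
differentiation_axis <- function(events, channels = NULL) {
  num <- names(events)[vapply(events, is.numeric, TRUE)]
  channels <- channels %||% num[1:2]
  if (length(channels) != 2L || !all(channels %in% names(events))) {
    abort("`channels` must name two event columns.")
  }
  x <- as.matrix(events[channels])
  if (nrow(x) < 2L) abort("Need at least 2 events.")
  if (any(!is.finite(x))) abort("Non-finite event values.")
  ctr <- colMeans(x)
  S <- cov(x)
  eg <- eigen(S, symmetric = TRUE)
  if (isTRUE(all.equal(eg$values[1], eg$values[2]))) {
    warn("Equal eigenvalues: co-induction axis tie broken toward the diagonal.")
    load <- c(1, 1) / sqrt(2)
  } else {
    load <- eg$vectors[, 1]
  }
  # orient toward co-induction: both non-negative when possible, else
  # dominant loading positive
  if (all(load <= 0)) load <- -load
  if (any(load < 0) && any(load > 0) && sum(load) < 0) load <- -load
  proj <- as.vector(sweep(x, 2, ctr) %*% load)
  structure(list(loadings = setNames(load, channels), center = ctr,
                 sdev = sqrt(pmax(eg$values, 0)),
                 var_explained = eg$values[1] / sum(eg$values),
                 projections = proj, events = events, channels = channels),
            class = "diff_axis")
}

#' @export
print.diff_axis <- function(x, ...) {
  cat(sprintf("<diff_axis> loadings (%s, %s) = (%.3f, %.3f), %.1f%% variance\n",
              x$channels[1], x$channels[2], x$loadings[1], x$loadings[2],
              100 * x$var_explained))
  invisible(x)
}

#' Project new events on a differentiation axis
#'
#' @param axis A `diff_axis`.
#' @param events Event tibble containing the axis channels.
#' @return Numeric vector of projections (centered by the axis center).
#' @export
project_events <- function(axis, events) {
  x <- as.matrix(events[axis$channels])
  as.vector(sweep(x, 2, axis$center) %*% axis$loadings)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param x Numeric vector (e.g. per-event axis projections).
#' @param level Confidence level (default 0.99).
#' @param n_boot Bootstrap resamples (default 10000; below 100 a warning is
#'   issued).
#' @param seed Optional integer seed.
#' @return A tibble `mean`, `lower`, `upper`, `level`, `n`, `n_boot`.
#' @export
bootstrap_mean_ci <- function(x, level = 0.99, n_boot = 10000, seed = NULL) {
  if (length(x) < 2L) abort("Need at least 2 observations.")
  level <- check_number(level, "level", 0.5, 1 - 1e-12)
  n_boot <- check_positive_int(n_boot, "n_boot")
  if (n_boot < 100) warn("Fewer than 100 bootstrap resamples.")
  n <- length(x)
  with_seed(seed, {
    means <- numeric(n_boot)
    chunk <- max(1L, min(n_boot, floor(2e7 / n)))
    done <- 0L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      means[done + seq_len(k)] <-
        colMeans(matrix(x[sample.int(n, n * k, replace = TRUE)], nrow = n))
      done <- done + k
    }
    qs <- quantile(means, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
    tibble(mean = mean(x), lower = qs[1], upper = qs[2], level = level,
           n = n, n_boot = n_boot)
  })
}

#' Two-sided Mann-Whitney U comparison
#'
#' Compares two groups of measurements (axis projections, per-cell
#' persistence, speeds, ...) with the two-sided Mann-Whitney U test: exact
#' when both groups have at most 8 untied observations, otherwise the
#' tie-corrected normal approximation.
#'
#' @param a,b Numeric vectors.
#' @return A tibble `statistic` (U for the first group), `p_value`,
#'   `n_a`, `n_b`, `method`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
compare_groups <- function(a, b) {
  if (!length(a) || !length(b)) abort("Both groups must be non-empty.")
  if (length(unique(c(a, b))) == 1L) {
    warn("All values identical across groups; p = 1.")
    return(tibble(statistic = length(a) * length(b) / 2, p_value = 1,
                  n_a = length(a), n_b = length(b), method = "degenerate"))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 8L && length(b) <= 8L
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = FALSE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(a), n_b = length(b),
         method = if (exact) "exact" else "normal approximation")
}
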