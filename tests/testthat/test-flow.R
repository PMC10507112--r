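test_that("the co-induction axis recovers canonical geometries", {
  # perfectly correlated channels -> diagonal up to sign
  set.seed(121)
  z <- rnorm(500)
  ev <- tibble::tibble(ch1 = z, ch2 = z)
  ax <- differentiation_axis(ev)
  expect_equal(abs(unname(ax$loadings)), c(1, 1) / sqrt(2), tolerance = 1e-6)
  expect_true(all(ax$loadings >= 0))
  # variance only in channel 2 -> axis (0, 1)
  ev2 <- tibble::tibble(ch1 = rep(1, 300), ch2 = rnorm(300))
  ax2 <- differentiation_axis(ev2)
  expect_equal(abs(unname(ax2$loadings)), c(0, 1), tolerance = 1e-6)
  # exactly equal eigenvalues tie-break toward the diagonal with a warning
  ev3 <- tibble::tibble(ch1 = c(1, -1, 0, 0), ch2 = c(0, 0, 1, -1))
  expect_warning(ax3 <- differentiation_axis(ev3), "tie")
  expect_equal(unname(ax3$loadings), c(1, 1) / sqrt(2))
})

test_that("axis analysis is channel-order invariant and variance-faithful", {
  fl <- simulate_flow(2000, mean = c(2, 2.3),
                      cov = matrix(c(0.06, 0.04, 0.04, 0.05), 2), seed = 122)
  ax <- differentiation_axis(fl)
  swapped <- fl[, c("ch2", "ch1")]
  ax_sw <- differentiation_axis(swapped)
  expect_equal(unname(ax$loadings[c("ch2", "ch1")]),
               unname(ax_sw$loadings), tolerance = 1e-9)
  expect_equal(ax$projections, ax_sw$projections, tolerance = 1e-9)
  # projection variance equals the leading eigenvalue
  expect_equal(var(ax$projections), ax$sdev[1]^2, tolerance = 1e-9)
})

test_that("a known co-induction shift is recovered on the axis", {
  delta <- 0.4
  a <- simulate_flow(4000, shift = 0, seed = 123)
  b <- simulate_flow(4000, shift = delta, seed = 124)
  pooled <- dplyr::bind_rows(a, b)
  ax <- differentiation_axis(pooled)
  pa <- ax$projections[seq_len(nrow(a))]
  pb <- ax$projections[-seq_len(nrow(a))]
  se <- sqrt(var(pa) / length(pa) + var(pb) / length(pb))
  expect_lt(abs((mean(pb) - mean(pa)) - delta), 3 * se + 0.02)
})

test_that("polygon gating matches a brute-force point-in-polygon oracle", {
  set.seed(125)
  ev <- tibble::tibble(ch1 = runif(400, -1, 2), ch2 = runif(400, -1, 2))
  poly <- cbind(c(0, 1.5, 1.2, 0.2), c(0, 0.2, 1.4, 1.1))
  gated <- suppressMessages(gate_events(ev, poly))
  # ray-casting oracle
  inside <- function(px, py) {
    n <- nrow(poly); j <- n; odd <- FALSE
    for (i in seq_len(n)) {
      if ((poly[i, 2] > py) != (poly[j, 2] > py) &&
          px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
            (poly[j, 2] - poly[i, 2]) + poly[i, 1]) odd <- !odd
      j <- i
    }
    odd
  }
  oracle <- mapply(inside, ev$ch1, ev$ch2)
  expect_equal(nrow(gated), sum(oracle))
  expect_equal(gated$ch1, ev$ch1[oracle])
})

test_that("all-in and all-out gates behave and degenerate gates error", {
  ev <- tibble::tibble(ch1 = runif(50), ch2 = runif(50))
  all_in <- suppressMessages(gate_events(ev, cbind(c(-1, 2, 2, -1),
                                                   c(-1, -1, 2, 2))))
  expect_equal(nrow(all_in), 50)
  expect_warning(suppressMessages(
    gate_events(ev, cbind(c(5, 6, 6, 5), c(5, 5, 6, 6)))), "no events")
  expect_error(gate_events(ev, cbind(c(0, 1), c(0, 1))), "Degenerate")
  expect_error(gate_events(ev, list(center = c(0, 0), shape = diag(2),
                                    radius = 0)), "Degenerate")
  ell <- suppressMessages(gate_events(ev, list(center = c(0.5, 0.5),
                                               shape = diag(2) * 0.04,
                                               radius = 1)))
  expect_true(all((ell$ch1 - 0.5)^2 + (ell$ch2 - 0.5)^2 < 0.04))
})

test_that("bootstrap CI is exact on constants and calibrated on Gaussians", {
  cc <- bootstrap_mean_ci(rep(2.5, 40), n_boot = 500, seed = 126)
  expect_equal(cc$lower, 2.5)
  expect_equal(cc$upper, 2.5)
  # width ~ 2 * z_{0.995} / sqrt(n) for standard normal data
  set.seed(127)
  x <- rnorm(1e4)
  ci <- bootstrap_mean_ci(x, level = 0.99, n_boot = 4000, seed = 128)
  expect_lt(abs((ci$upper - ci$lower) / (2 * 2.576 / sqrt(1e4)) - 1), 0.1)
  expect_warning(bootstrap_mean_ci(x[1:10], n_boot = 50, seed = 1), "100")
})

test_that("bootstrap CI width shrinks as 1/sqrt(n)", {
  set.seed(129)
  x <- rnorm(6400)
  w <- vapply(c(400, 1600, 6400), function(n) {
    ci <- bootstrap_mean_ci(x[seq_len(n)], n_boot = 2000, seed = n)
    ci$upper - ci$lower
  }, 0)
  expect_lt(abs(w[1] / w[2] - 2), 0.4)
  expect_lt(abs(w[2] / w[3] - 2), 0.4)
})

test_that("Mann-Whitney comparisons match enumeration and handle ties", {
  out <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, 0)   # U = 0 in one direction
  expect_equal(out$p_value, 0.1)   # 2/20 of all rankings as extreme
  expect_equal(out$method, "exact")
  expect_warning(same <- compare_groups(rep(1, 5), rep(1, 5)), "identical")
  expect_equal(same$p_value, 1)
  # shifted Gaussians separate decisively at n = 100
  set.seed(130)
  hits <- vapply(1:20, function(i) {
    compare_groups(rnorm(100), rnorm(100, 1))$p_value < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("simulate_flow validates covariance and stores truth", {
  expect_error(simulate_flow(10, cov = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  fl <- simulate_flow(100, shift = 0.3, axis = c(3, 4), seed = 131)
  tr <- attr(fl, "truth")
  expect_equal(tr$axis, c(3, 4) / 5)
  expect_equal(tr$shift, 0.3)
})
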