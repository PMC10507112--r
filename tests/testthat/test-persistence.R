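test_that("step log-likelihood matches the Gaussian density in closed form", {
  # at the mode the density is -(d/2) log(2 pi a^2)
  for (d in 2:3) {
    vp <- rep(0.2, d); q <- 0.6; a <- 0.15
    expect_equal(hrw_loglik(q * vp, vp, q, a), -(d / 2) * log(2 * pi * a^2))
    # doubling a at the mode lowers the log density by d log 2
    expect_equal(hrw_loglik(q * vp, vp, q, a) -
                   hrw_loglik(q * vp, vp, q, 2 * a), d * log(2))
  }
  # random inputs against an independent product-normal oracle
  set.seed(111)
  for (i in 1:20) {
    d <- sample(2:3, 1)
    vn <- rnorm(d); vp <- rnorm(d); q <- runif(1, -1, 1); a <- runif(1, .01, .5)
    oracle <- -d / 2 * log(2 * pi * a^2) - sum((vn - q * vp)^2) / (2 * a^2)
    expect_equal(hrw_loglik(vn, vp, q, a), oracle, tolerance = 1e-10)
  }
  expect_equal(hrw_loglik(c(0.3, 0), c(0.6, 0), q = 0.5, a = 0), Inf)
  expect_equal(hrw_loglik(c(0.3, 0.1), c(0.6, 0), q = 0.5, a = 0), -Inf)
})

test_that("the filter recovers constant parameters on long tracks", {
  tr <- simulate_tracks(3, 500, q = 0.8, a = 0.2, seed = 112)
  fit <- infer_persistence(tr)
  expect_lt(abs(mean(fit$cells$mean_q) - 0.8), 0.1)
  expect_lt(abs(mean(fit$cells$mean_a) - 0.2), 0.05)
})

test_that("pure-noise tracks show no persistence", {
  tr <- simulate_tracks(100, 60, q = 0, a = 0.2, seed = 113)
  fit <- infer_persistence(tr, grid = hrw_grid(grid_size = 60))
  expect_lt(abs(mean(fit$cells$mean_q)), 0.1)
})

test_that("a mid-track persistence step change flips the estimate quickly", {
  n_steps <- 300
  sched <- matrix(c(rep(0.8, 150), rep(-0.5, 150)), 1, n_steps)
  tr <- simulate_tracks(1, n_steps, q = sched,
                        a = matrix(0.2, 1, n_steps), seed = 114)
  fit <- infer_persistence(tr)
  qhat <- fit$steps$q_hat
  expect_gt(mean(qhat[100:150]), 0.5)
  flip_at <- which(sign(qhat) < 0 & seq_along(qhat) > 150)[1]
  expect_lt(flip_at - 150, 20)
  expect_lt(mean(qhat[200:299]), -0.3)
})

test_that("with p_min near 1 the posterior resets to uniform each step", {
  tr <- simulate_tracks(2, 80, q = 0.9, a = 0.2, seed = 115)
  v <- track_velocities(tr)
  v1 <- as.matrix(v[v$cell == 1, c("vx", "vy")])
  g1 <- hrw_grid(grid_size = 60, p_min = 1 - 1e-9)
  g0 <- hrw_grid(grid_size = 60, p_min = 1e-5)
  hi <- neutroscreen:::hrw_filter_cpp(v1, g1$q, g1$a, g1$p_min, g1$r_q, g1$r_a)
  lo <- neutroscreen:::hrw_filter_cpp(v1, g0$q, g0$a, g0$p_min, g0$r_q, g0$r_a)
  # propagated posterior is the uniform distribution
  expect_lt(max(abs(hi$posterior - 1 / 60^2)), 1e-8)
  # evidence cannot accumulate across steps: per-step estimates come from a
  # single likelihood and sit well below the full filter's
  expect_lt(mean(hi$q_hat), mean(lo$q_hat) - 0.05)
  # null tracks stay near zero persistence even per step
  tr0 <- simulate_tracks(2, 200, q = 0, a = 0.2, seed = 116)
  fit0 <- infer_persistence(tr0, grid = g1)
  expect_lt(abs(mean(fit0$cells$mean_q)), 0.1)
})

test_that("estimates are invariant to rigid rotation of the track", {
  tr <- simulate_tracks(2, 120, q = 0.6, a = 0.2, seed = 116)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- tr
  xy <- as.matrix(tr[c("x", "y")]) %*% t(R)
  rot$x <- xy[, 1]; rot$y <- xy[, 2]
  g <- hrw_grid(grid_size = 80)
  f1 <- infer_persistence(tr, grid = g)
  f2 <- infer_persistence(rot, grid = g)
  expect_equal(f1$cells$mean_q, f2$cells$mean_q, tolerance = 1e-8)
  expect_equal(f1$cells$mean_a, f2$cells$mean_a, tolerance = 1e-8)
})

test_that("posterior normalization is preserved at every step", {
  tr <- simulate_tracks(1, 50, q = 0.5, a = 0.2, seed = 117)
  v <- track_velocities(tr)
  g <- hrw_grid(grid_size = 50)
  fit <- neutroscreen:::hrw_filter_cpp(as.matrix(v[c("vx", "vy")]),
                                       g$q, g$a, g$p_min, g$r_q, g$r_a)
  expect_true(all(abs(rowSums(fit$q_marginal) - 1) < 1e-9))
  expect_true(all(abs(rowSums(fit$a_marginal) - 1) < 1e-9))
  expect_equal(sum(fit$posterior), 1, tolerance = 1e-9)
})

test_that("3D velocities enter the likelihood when requested", {
  tr <- simulate_tracks(2, 150, q = 0.7, a = 0.2, dims = 3, seed = 118)
  g <- hrw_grid(grid_size = 80)
  f3 <- infer_persistence(tr, grid = g, use_z = TRUE)
  f2 <- infer_persistence(tr, grid = g, use_z = FALSE)
  expect_lt(abs(mean(f3$cells$mean_q) - 0.7), 0.15)
  expect_lt(abs(mean(f2$cells$mean_q) - 0.7), 0.2)
})

test_that("group summaries and Mann-Whitney comparisons work on fits", {
  tr1 <- simulate_tracks(8, 150, q = 0.2, a = 0.2, seed = 119)
  tr2 <- simulate_tracks(8, 150, q = 0.7, a = 0.2, seed = 120)
  g <- hrw_grid(grid_size = 80)
  f1 <- infer_persistence(tr1, grid = g)
  f2 <- infer_persistence(tr2, grid = g)
  both <- summarize_persistence(f1, group = rep("ctrl", 8))
  expect_true("group" %in% names(both))
  expect_false(is.null(attr(both, "group_means")))
  cmp <- compare_groups(f1$cells$mean_q, f2$cells$mean_q)
  expect_lt(cmp$p_value, 0.01)
})
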