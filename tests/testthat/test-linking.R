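det_at <- function(xy) tibble::tibble(x = xy[, 1], y = xy[, 2])

test_that("singletons within the gate are matched", {
  lk <- link_frames(det_at(cbind(0, 0)), det_at(cbind(1, 1)), max_disp = 5)
  expect_equal(nrow(lk$matches), 1)
  expect_equal(lk$matches$dist, sqrt(2))
  expect_length(lk$births, 0)
  expect_length(lk$deaths, 0)
})

test_that("the crossing pair resolves to the minimum total displacement", {
  # two cells whose naive nearest-neighbour pairing would swap identities
  prev <- det_at(cbind(c(0, 10), c(0, 0)))
  nxt <- det_at(cbind(c(2, 8), c(0, 0)))
  lk <- link_frames(prev, nxt)
  bf <- brute_force_link(prev, nxt)
  expect_equal(nrow(lk$matches), bf$card)
  expect_equal(sum(lk$matches$dist), bf$cost)
  expect_equal(lk$matches$j[order(lk$matches$i)], c(1, 2))
})

test_that("assignments equal the brute-force optimum on random frames", {
  set.seed(91)
  for (trial in 1:25) {
    n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
    prev <- det_at(matrix(runif(2 * n1, 0, 30), ncol = 2))
    nxt <- det_at(matrix(runif(2 * n2, 0, 30), ncol = 2))
    gate <- sample(c(Inf, 15, 8), 1)
    lk <- link_frames(prev, nxt, max_disp = gate)
    bf <- brute_force_link(prev, nxt, max_disp = gate)
    expect_equal(nrow(lk$matches), bf$card,
                 info = sprintf("trial %d cardinality", trial))
    expect_equal(sum(lk$matches$dist), bf$cost, tolerance = 1e-8,
                 info = sprintf("trial %d cost", trial))
    expect_true(all(lk$matches$dist <= gate))
  }
})

test_that("displacements beyond the gate become death plus birth", {
  lk <- link_frames(det_at(cbind(0, 0)), det_at(cbind(50, 0)), max_disp = 10)
  expect_equal(nrow(lk$matches), 0)
  expect_equal(lk$deaths, 1)
  expect_equal(lk$births, 1)
})

test_that("linking is invariant to detection order", {
  set.seed(92)
  prev <- det_at(matrix(runif(10, 0, 20), ncol = 2))
  nxt <- det_at(matrix(runif(10, 0, 20), ncol = 2))
  lk1 <- link_frames(prev, nxt, max_disp = Inf)
  perm <- sample(5)
  lk2 <- link_frames(prev, nxt[perm, ], max_disp = Inf)
  # map permuted indices back
  j_back <- perm[lk2$matches$j]
  expect_equal(sum(lk1$matches$dist), sum(lk2$matches$dist), tolerance = 1e-8)
  expect_setequal(paste(lk1$matches$i, lk1$matches$j),
                  paste(lk2$matches$i, j_back))
})

test_that("build_tracks reconstructs well-separated ground-truth tracks", {
  tr <- simulate_tracks(6, 12, q = 0.3, a = 0.05, dt = 60, seed = 93)
  tr <- neutroscreen:::recenter_tracks(tr, margin = 10)
  det <- dplyr::select(tr, t, x, y)
  tracks <- build_tracks(det, max_disp = 25, pixel_size = 1, dt = 60)
  expect_equal(length(unique(tracks$cell)), 6)
  lens <- table(tracks$cell)
  expect_true(all(lens == 13))
  expect_equal(nrow(tracks), nrow(det))  # conservation of detections
})

test_that("a single-frame movie yields length-1 tracks", {
  det <- tibble::tibble(t = 0L, x = c(1, 5, 9), y = c(1, 5, 9))
  tracks <- build_tracks(det, dt = 1)
  expect_equal(length(unique(tracks$cell)), 3)
  expect_true(all(table(tracks$cell) == 1))
})
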