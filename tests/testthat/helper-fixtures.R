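# Shared fixtures, built in code at test time.

tiny_library <- function(n_genes = 10, n_controls = 20, seed = 42) {
  simulate_guide_library(n_genes, n_controls = n_controls, seed = seed)
}

# Hand-built read batch with known sequences/qualities.
batch_of <- function(sequences, qualities) {
  out <- tibble::tibble(sequence = sequences, quality = qualities)
  class(out) <- c("read_batch", class(out))
  out
}

# Brute-force minimum-total-displacement assignment by enumerating every
# injection of the smaller side into the larger, subject to the gate.
# Maximum cardinality first, then minimum summed distance.
brute_force_link <- function(prev, nxt, max_disp = Inf) {
  axes <- intersect(c("x", "y", "z"), intersect(names(prev), names(nxt)))
  a <- as.matrix(prev[axes]); b <- as.matrix(nxt[axes])
  n1 <- nrow(a); n2 <- nrow(b)
  d <- matrix(0, n1, n2)
  for (k in seq_len(ncol(a))) d <- d + outer(a[, k], b[, k], "-")^2
  d <- sqrt(d)
  best <- list(card = -1L, cost = Inf, pairs = NULL)
  subsets <- function(n, k) utils::combn(n, k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  for (k in seq(min(n1, n2), 0L)) {
    if (k == 0L) {
      if (best$card < 0L) best <- list(card = 0L, cost = 0, pairs = NULL)
      break
    }
    for (si in subsets(n1, k)) for (sj in subsets(n2, k)) {
      for (pj in perms(sj)) {
        dists <- d[cbind(si, pj)]
        if (any(dists > max_disp)) next
        cost <- sum(dists)
        if (k > best$card || (k == best$card && cost < best$cost)) {
          best <- list(card = k, cost = cost,
                       pairs = if (k) cbind(i = si, j = pj) else NULL)
        }
      }
    }
    if (best$card == k) break
  }
  best
}
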