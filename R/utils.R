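# Internal helpers shared across modules.

# Reserved target label carried by non-targeting control guides.
CONTROL_LABEL <- "control"

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG stream is untouched. `seed = NULL` uses (and advances) the
# current stream, so callers keep full control of reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Spawn a reproducible sub-seed for stage `k` of a multi-stage run rooted at
# `seed`. Kept well below .Machine$integer.max.
substream <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483587L
}

check_positive_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  as.numeric(x)
}

# Mean Phred score per read from Phred+33 quality strings. One utf8ToInt
# pass over the concatenated strings keeps this O(total bases).
phred_means <- function(quality) {
  if (length(quality) == 0L) return(numeric(0))
  lens <- nchar(quality)
  scores <- utf8ToInt(paste(quality, collapse = "")) - 33L
  as.numeric(rowsum(scores, rep(seq_along(quality), lens))) / lens
}
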