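# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic per-stream seed derived from a master seed; streams indexed by
# a small non-negative integer.  Kept below 2^31 - 1 so set.seed() accepts it.
substream_seed <- function(seed, stream) {
  (abs(as.numeric(seed)) + 1000003 * as.numeric(stream)) %% 2147483647
}

# Deterministic seed for a named subject derived from the master seed.
subject_seed <- function(seed, id) {
  h <- sum(as.numeric(utf8ToInt(as.character(id))) *
             (31 ^ (seq_along(utf8ToInt(as.character(id))) %% 7))) %% 1000003
  substream_seed(seed, h)
}

# round() uses banker's rounding; goodness-of-fit ranking needs
# round-half-away-from-zero so that e.g. 0.9995 rounds to 1.000.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Power of 2 nearest to x in log2 (geometric) space; ties round up.
# `next` instead takes the smallest power of 2 >= x.
pow2_round <- function(x, rule = c("nearest", "next")) {
  rule <- match.arg(rule)
  stopifnot(all(x > 0))
  k <- switch(rule,
    nearest = floor(log2(x) + 0.5),
    `next`  = ceiling(log2(x) - 1e-12)
  )
  2^k
}
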