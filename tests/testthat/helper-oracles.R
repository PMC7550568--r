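# Independent reference implementations used as oracles.  These deliberately
# share no code path with the package: closed-form OLS instead of lm(),
# array-slicing cell enumeration instead of coordinate packing, plain loops
# instead of vectorised ranking.

# Closed-form simple linear regression of ly on lx.
oracle_ols <- function(lx, ly) {
  n <- length(lx)
  mx <- mean(lx); my <- mean(ly)
  sxx <- sum((lx - mx)^2)
  sxy <- sum((lx - mx) * (ly - my))
  syy <- sum((ly - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
  list(slope = slope, intercept = my - slope * mx, r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# Brute-force box count: enumerate every grid cell by its voxel span and
# test occupancy with array slicing.  Cell origins are at -offset + k*s
# (0-based voxel coordinates).
oracle_count <- function(arr, s, offset) {
  d <- dim(arr)
  n <- 0L
  for (x0 in seq(-offset[1], d[1] - 1, by = s))
    for (y0 in seq(-offset[2], d[2] - 1, by = s))
      for (z0 in seq(-offset[3], d[3] - 1, by = s)) {
        xs <- max(x0, 0):min(x0 + s - 1, d[1] - 1) + 1L
        ys <- max(y0, 0):min(y0 + s - 1, d[2] - 1) + 1L
        zs <- max(z0, 0):min(z0 + s - 1, d[3] - 1) + 1L
        if (any(arr[xs, ys, zs] != 0)) n <- n + 1L
      }
  n
}

# Exact mean count over all s^3 integer offsets.
oracle_exhaustive_mean <- function(arr, s) {
  counts <- numeric(0)
  for (ox in 0:(s - 1)) for (oy in 0:(s - 1)) for (oz in 0:(s - 1))
    counts <- c(counts, oracle_count(arr, s, c(ox, oy, oz)))
  mean(counts)
}

oracle_round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p  # all r2_adj values here are >= 0
}

# Brute-force scale-interval selection: enumerate, fit, rank with explicit
# pairwise comparisons.  mode "maxr2": highest unrounded r2_adj, first in
# (start, end) enumeration order on ties.  mode "roundedr2": highest rounded
# r2_adj, then widest in decades, then smallest mfs.
oracle_select <- function(scales_mm, counts, min_points, mode,
                          round_places = 3) {
  n <- length(scales_mm)
  best <- NULL
  for (i in 1:(n - min_points + 1)) {
    for (j in (i + min_points - 1):n) {
      f <- oracle_ols(log10(scales_mm[i:j]), log10(counts[i:j]))
      cand <- list(i = i, j = j, fd = abs(f$slope), r2_adj = f$r2_adj,
                   rr = oracle_round_half_up(f$r2_adj, round_places),
                   width = log10(scales_mm[j] / scales_mm[i]),
                   mfs = scales_mm[i])
      if (is.null(best)) { best <- cand; next }
      better <- if (mode == "maxr2") {
        cand$r2_adj > best$r2_adj
      } else {
        if (cand$rr != best$rr) cand$rr > best$rr
        else if (cand$width != best$width) cand$width > best$width
        else cand$mfs < best$mfs
      }
      if (better) best <- cand
    }
  }
  best
}

# Construct an fd_curve from given mean counts (fixture curves for the
# selection strategies; spacing 1 mm so voxel scales equal mm scales).
make_curve <- function(counts, scales = 2^(seq_along(counts) - 1)) {
  structure(
    list(scales = as.integer(scales), scales_mm = as.numeric(scales),
         mean_counts = as.numeric(counts), n_offsets = 0L, seed = 0,
         spacing = 1, n_foreground = ceiling(max(counts)),
         per_offset_counts = NULL),
    class = "fd_curve"
  )
}

# Random log-log curves: linear trend plus Gaussian roughness of varying
# amplitude (occasionally pure noise), always positive counts.
random_curve <- function(seed) {
  set.seed(seed)
  lx <- log10(2^(0:8))
  slope <- runif(1, -3, -1.5)
  noise <- runif(1, 0, 0.2)
  ly <- if (runif(1) < 0.1) runif(9, 0, 6) else 6 + slope * lx + rnorm(9, 0, noise)
  make_curve(10^ly)
}

# Independent k-fold CV reference following the documented procedure:
# shuffle with sample.int, contiguous folds with the remainder spread one
# per fold, training-fold-only standardization, OLS via the normal
# equations.  Returns per-row absolute errors in original row order.
oracle_cv_abs_errors <- function(X, y, n_folds) {
  n <- length(y)
  ord <- sample.int(n)
  sizes <- rep(n %/% n_folds, n_folds)
  if (n %% n_folds > 0) sizes[seq_len(n %% n_folds)] <- sizes[1] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, stops[-n_folds] + 1L)
  abs_err <- numeric(n)
  for (f in seq_len(n_folds)) {
    te <- ord[starts[f]:stops[f]]
    tr <- setdiff(ord, te)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    std <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
    A <- cbind(1, std(X[tr, , drop = FALSE]))
    beta <- solve(t(A) %*% A, t(A) %*% y[tr])
    pred <- drop(cbind(1, std(X[te, , drop = FALSE])) %*% beta)
    abs_err[te] <- abs(pred - y[te])
  }
  abs_err
}

# Small seeded random volume with guaranteed nonempty foreground.
random_volume <- function(side, p = 0.2, seed = 1) {
  set.seed(seed)
  a <- array(as.integer(runif(side^3) < p), c(side, side, side))
  if (sum(a) == 0) a[1, 1, 1] <- 1L
  voxel_volume(a)
}
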