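#' Interval width in decades
#'
#' The width of a scale interval \[mfs, Mfs\] in decades (factors of 10):
#' `log10(Mfs / mfs)`.  Reporting layers round to 1 decimal; e.g.
#' \[1, 8\] mm covers 0.903 decades, reported as 0.9.
#'
#' @param mfs,Mfs minimum and maximum fractal scale in mm, `0 < mfs < Mfs`.
#' @return Width in decades (unrounded).
#' @export
width_decades <- function(mfs, Mfs) {
  if (any(mfs <= 0) || any(Mfs <= mfs))
    stop("InvalidBounds: need 0 < mfs < Mfs")
  log10(Mfs / mfs)
}

# Internal constructor for a contiguous scale interval.
scale_interval <- function(curve, indices) {
  indices <- as.integer(indices)
  if (length(indices) < 2L ||
      any(indices < 1L) || any(indices > length(curve$scales)) ||
      !all(diff(indices) == 1L))
    stop("IntervalOutOfRange: indices must be >= 2 contiguous valid positions")
  mfs <- curve$scales_mm[indices[1L]]
  Mfs <- curve$scales_mm[indices[length(indices)]]
  structure(
    list(indices = indices, mfs = mfs, Mfs = Mfs,
         n_points = length(indices),
         width_decades = width_decades(mfs, Mfs)),
    class = "scale_interval"
  )
}

#' @export
print.scale_interval <- function(x, ...) {
  cat(sprintf("scale_interval: [%g, %g] mm, %d points, %.3f decades\n",
              x$mfs, x$Mfs, x$n_points, x$width_decades))
  invisible(x)
}

#' Enumerate candidate scale intervals
#'
#' All contiguous windows of at least `min_points` scales, in deterministic
#' order (by start index, then end index).  This is the search space of the
#' automated selection strategies, which fit a regression on every window.
#'
#' @param curve an [fd_boxcount()] curve.
#' @param min_points minimum number of log-log data points per window
#'   (`>= 2`).
#' @return List of `scale_interval` objects.
#' @examples
#' crv <- fd_boxcount(phantom_cube(16), scales = 2^(0:4), n_offsets = 0)
#' length(enumerate_intervals(crv, min_points = 5))  # 1
#' @export
enumerate_intervals <- function(curve, min_points = 2) {
  n <- length(curve$scales)
  if (min_points < 2) stop("InvalidParams: min_points must be >= 2")
  if (n < min_points)
    stop("TooFewScales: ", n, " scales < min_points = ", min_points)
  out <- list()
  for (i in seq_len(n - min_points + 1L))
    for (j in (i + min_points - 1L):n)
      out[[length(out) + 1L]] <- scale_interval(curve, i:j)
  out
}

#' Log-log power-law fit over a scale interval
#'
#' Ordinary least squares of `log10 N(s)` on `log10 s` restricted to the
#' interval.  In natural scale this is the power law N(s) = C s^-FD: the
#' fractal dimension is the absolute value of the slope and the prefactor
#' C is `10^intercept`.  The goodness of fit is summarised by R^2 and by
#' R^2 adjusted for the number of data points, which for a one-predictor
#' regression is `1 - (1 - R^2) (n - 1) / (n - 2)`.
#'
#' @param curve an [fd_boxcount()] curve with positive counts.
#' @param interval a `scale_interval`, or an integer vector of contiguous
#'   indices into the curve's scales.
#' @return An object of class `loglog_fit`: slope, intercept (log10 C),
#'   `fd` = |slope|, `r2`, `r2_adj`, `n_points`, plus the interval.
#' @examples
#' crv <- fd_boxcount(phantom_cube(64), scales = 2^(0:5), n_offsets = 0)
#' fit_loglog(crv, 1:6)$fd  # 3
#' @export
fit_loglog <- function(curve, interval) {
  if (!inherits(interval, "scale_interval"))
    interval <- scale_interval(curve, interval)
  idx <- interval$indices
  y <- curve$mean_counts[idx]
  if (any(y <= 0)) stop("InvalidCounts: counts must be positive for log fit")
  lx <- log10(curve$scales_mm[idx])
  if (length(unique(lx)) < 2L)
    stop("DegenerateInterval: fewer than 2 distinct scales")
  fit <- stats::lm(log10(y) ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  n <- length(idx)
  # R^2 from the residuals directly: summary.lm() warns on the exact power
  # laws of analytic phantoms ("essentially perfect fit").
  tss <- sum((log10(y) - mean(log10(y)))^2)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         fd = abs(slope),
         r2 = r2,
         r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
         n_points = n,
         interval = interval),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("loglog_fit: FD = %.4f over [%g, %g] mm (%d points), R2_adj = %.4f\n",
              x$fd, x$interval$mfs, x$interval$Mfs, x$n_points, x$r2_adj))
  invisible(x)
}

#' Select the interval of fractal spatial scales
#'
#' Four strategies decide which contiguous window of sampled scales the
#' log-log regression is fitted on:
#'
#' * `"fixed"` — an a-priori range in mm (default \[4, 256\]), motivated
#'   by the span from typical cortical thickness to head size; both bounds
#'   must be sampled scales.
#' * `"bbox"` — an a-priori range derived from the object: 5% and 40% of
#'   the shortest side of the foreground bounding box, each rounded to a
#'   power of 2 (`rounding = "nearest"` in log2 space, ties up, or
#'   `"next"` for the smallest power of 2 above), then clipped to the
#'   sampled scales.  Requires `vol`.
#' * `"maxr2"` — automated: fits every window of at least `min_points`
#'   (default 4) points and returns the one with the highest unrounded
#'   adjusted R^2; ties broken by enumeration order.
#' * `"roundedr2"` — improved automated selection: only the first 3
#'   decimals of adjusted R^2 are treated as effective (one decimal place
#'   of a percentage), so windows are ranked by adjusted R^2 rounded
#'   half-away-from-zero to `round_places` decimals, then by width in
#'   decades (widest first), then by smallest mfs.  Requires at least
#'   `min_points` (default 5) points per window so any candidate spans at
#'   least 1.2 decades on the dyadic scale set.
#'
#' @param curve an [fd_boxcount()] curve.
#' @param strategy one of `"fixed"`, `"bbox"`, `"maxr2"`, `"roundedr2"`.
#' @param vol the [voxel_volume] (required for `"bbox"`).
#' @param mfs,Mfs fixed bounds in mm for `"fixed"`.
#' @param min_points minimum points per window for the automated
#'   strategies (defaults: 4 for `"maxr2"`, 5 for `"roundedr2"`).
#' @param round_places decimals kept of adjusted R^2 for `"roundedr2"`
#'   (default 3).
#' @param rounding power-of-2 rounding rule for `"bbox"`.
#' @return A list with `interval` (`scale_interval`) and `fit`
#'   (`loglog_fit`).
#' @export
select_scales <- function(curve,
                          strategy = c("roundedr2", "maxr2", "fixed", "bbox"),
                          vol = NULL, mfs = 4, Mfs = 256,
                          min_points = NULL, round_places = 3,
                          rounding = c("nearest", "next")) {
  strategy <- match.arg(strategy)
  interval <- switch(strategy,
    fixed = select_fixed(curve, mfs, Mfs),
    bbox = select_bbox(curve, vol, match.arg(rounding)),
    maxr2 = ,
    roundedr2 = NULL
  )
  if (!is.null(interval))
    return(list(interval = interval, fit = fit_loglog(curve, interval)))

  if (is.null(min_points))
    min_points <- if (strategy == "maxr2") 4L else 5L
  fits <- lapply(enumerate_intervals(curve, min_points),
                 function(iv) fit_loglog(curve, iv))
  best <- if (strategy == "maxr2") {
    fits[[which.max(vapply(fits, `[[`, numeric(1), "r2_adj"))]]
  } else {
    key <- data.frame(
      r2r = round_half_up(vapply(fits, `[[`, numeric(1), "r2_adj"), round_places),
      wid = vapply(fits, function(f) f$interval$width_decades, numeric(1)),
      mfs = vapply(fits, function(f) f$interval$mfs, numeric(1))
    )
    fits[[order(-key$r2r, -key$wid, key$mfs)[1L]]]
  }
  list(interval = best$interval, fit = best)
}

select_fixed <- function(curve, mfs, Mfs) {
  if (mfs >= Mfs) stop("InvalidBounds: need mfs < Mfs")
  tol <- 1e-9
  if (!any(abs(curve$scales_mm - mfs) < tol) ||
      !any(abs(curve$scales_mm - Mfs) < tol))
    stop("BoundsNotSampled: mfs and Mfs must be sampled scales (mm)")
  idx <- which(curve$scales_mm >= mfs - tol & curve$scales_mm <= Mfs + tol)
  scale_interval(curve, idx)
}

select_bbox <- function(curve, vol, rounding) {
  if (is.null(vol)) stop("InvalidParams: strategy 'bbox' needs `vol`")
  coords <- fg_coords(vol)
  extent_vox <- apply(coords, 2, function(v) max(v) - min(v) + 1)
  shortest_mm <- min(extent_vox) * vol$spacing[1L]
  mfs <- pow2_round(0.05 * shortest_mm, rounding)
  Mfs <- pow2_round(0.40 * shortest_mm, rounding)
  if (mfs >= Mfs)
    stop("DegenerateInterval: rounded bounds collapse (mfs >= Mfs)")
  idx <- which(curve$scales_mm >= mfs - 1e-9 & curve$scales_mm <= Mfs + 1e-9)
  if (length(idx) < 2L)
    stop("DegenerateInterval: fewer than 2 sampled scales in [",
         mfs, ", ", Mfs, "] mm")
  scale_interval(curve, idx)
}
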