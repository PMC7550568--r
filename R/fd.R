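#' Estimate the fractal dimension of a voxel volume
#'
#' The central fitting function: computes (or reuses) the offset-averaged
#' box-count curve, selects the interval of fractal spatial scales with
#' the requested strategy, and fits the log-log power law
#' N(s) = C s^-FD over that interval.  FD is the absolute slope of the
#' ordinary least-squares line of log10 N(s) on log10 s.
#'
#' The curve depends only on the volume, not on the strategy, so when
#' comparing strategies on the same subject pass a precomputed
#' [fd_boxcount()] curve: the comparison is then count-identical.
#'
#' @param x a [voxel_volume] or a precomputed `fd_curve`.
#' @param strategy scale-interval selection strategy; see
#'   [select_scales()].
#' @param scales box sides in voxels (ignored when `x` is a curve).
#' @param n_offsets random grid origins per scale (default 20; 0 = exact
#'   aligned mode).  Ignored when `x` is a curve.
#' @param seed RNG seed for the offset draws.
#' @param vol the volume, required for `strategy = "bbox"` when `x` is a
#'   curve.
#' @param subject_id optional identifier carried into the report.
#' @param ... further arguments to [select_scales()] (`mfs`, `Mfs`,
#'   `min_points`, `round_places`, `rounding`).
#' @return An object of class `fd_fit` with components `fd`, `mfs`, `Mfs`
#'   (mm), `width_decades`, `r2`, `r2_adj`, `prefactor`, `slope`,
#'   `intercept`, the selected `interval`, the full `curve`, `strategy`
#'   and provenance (`n_offsets`, `seed`, `version`).  A fitted dimension
#'   above 3 by more than 0.1 triggers a warning (offset averaging can
#'   push local slopes slightly above 3 on degenerate objects) but is
#'   never an error.
#' @examples
#' fit <- fd_fit(phantom_cube(64), strategy = "roundedr2",
#'               scales = 2^(0:5), n_offsets = 0)
#' coef(fit)
#' @export
fd_fit <- function(x, strategy = c("roundedr2", "maxr2", "fixed", "bbox"),
                   scales = default_scales(), n_offsets = 20, seed = 1,
                   vol = NULL, subject_id = NA_character_, ...) {
  strategy <- match.arg(strategy)
  if (inherits(x, "voxel_volume")) {
    vol <- x
    curve <- fd_boxcount(x, scales = scales, n_offsets = n_offsets, seed = seed)
  } else if (inherits(x, "fd_curve")) {
    curve <- x
  } else {
    stop("InvalidInput: `x` must be a voxel_volume or an fd_curve")
  }
  sel <- select_scales(curve, strategy = strategy, vol = vol, ...)
  fit <- sel$fit
  if (fit$fd > 3 + 0.1)
    warning("fd = ", signif(fit$fd, 4),
            " exceeds the embedding dimension 3 by more than 0.1")
  structure(
    list(subject_id = subject_id,
         strategy = strategy,
         fd = fit$fd,
         mfs = fit$interval$mfs,
         Mfs = fit$interval$Mfs,
         width_decades = fit$interval$width_decades,
         r2 = fit$r2,
         r2_adj = fit$r2_adj,
         slope = fit$slope,
         intercept = fit$intercept,
         prefactor = 10^fit$intercept,
         interval = fit$interval,
         curve = curve,
         n_offsets = curve$n_offsets,
         seed = curve$seed,
         version = as.character(utils::packageVersion("fracdim3d"))),
    class = "fd_fit"
  )
}

#' @export
print.fd_fit <- function(x, ...) {
  cat("3-D box-counting fractal dimension fit\n")
  if (!is.na(x$subject_id)) cat("  subject:  ", x$subject_id, "\n")
  cat("  strategy: ", x$strategy, "\n")
  cat(sprintf("  FD = %.4f   (scales [%g, %g] mm, %.1f decades, %d points)\n",
              x$fd, x$mfs, x$Mfs, round(x$width_decades, 1),
              x$interval$n_points))
  cat(sprintf("  R2 = %.5f, R2_adj = %.5f, prefactor C = %.4g\n",
              x$r2, x$r2_adj, x$prefactor))
  invisible(x)
}

#' @export
summary.fd_fit <- function(object, ...) {
  out <- data.frame(
    subject_id = object$subject_id, strategy = object$strategy,
    fd = object$fd, mfs_mm = object$mfs, Mfs_mm = object$Mfs,
    width_decades = object$width_decades, n_points = object$interval$n_points,
    r2_adj = object$r2_adj, prefactor = object$prefactor,
    n_offsets = object$n_offsets, seed = object$seed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.fd_fit", "data.frame")
  out
}

#' @export
coef.fd_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted mean box counts from a fitted power law
#' @param object an `fd_fit`.
#' @param newdata scales in mm (default: the curve's sampled scales).
#' @param ... unused.
#' @return Predicted N(s) = C s^-FD on the natural scale.
#' @export
predict.fd_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$curve$scales_mm else newdata
  object$prefactor * s^(-object$fd)
}

#' @export
fitted.fd_fit <- function(object, ...) {
  idx <- object$interval$indices
  object$intercept + object$slope * log10(object$curve$scales_mm[idx])
}

#' @export
residuals.fd_fit <- function(object, ...) {
  idx <- object$interval$indices
  log10(object$curve$mean_counts[idx]) - fitted(object)
}

#' Log-log plot of the box-count curve with the fitted line
#' @param x an `fd_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fd_fit <- function(x, ...) {
  lx <- log10(x$curve$scales_mm)
  ly <- log10(x$curve$mean_counts)
  graphics::plot(lx, ly, pch = 1, xlab = "log10 s (mm)",
                 ylab = "log10 N(s)", ...)
  idx <- x$interval$indices
  graphics::points(lx[idx], ly[idx], pch = 19)
  graphics::abline(x$intercept, x$slope)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("FD = %.3f  [%g, %g] mm",
                                    x$fd, x$mfs, x$Mfs))
  invisible(x)
}

#' Serialize / restore an FD report
#'
#' `fd_report()` flattens an `fd_fit` into a plain list (curve included)
#' that [jsonlite::write_json()] round-trips at full double precision;
#' `write_fd_report()` and `read_fd_report()` do the file I/O.
#'
#' @param fit an `fd_fit`.
#' @return `fd_report()`: a named list; `read_fd_report()`: the list read
#'   back.
#' @export
fd_report <- function(fit) {
  stopifnot(inherits(fit, "fd_fit"))
  list(
    schema = "fracdim3d-report-1",
    subject_id = fit$subject_id, strategy = fit$strategy,
    fd = fit$fd, mfs_mm = fit$mfs, Mfs_mm = fit$Mfs,
    width_decades = fit$width_decades,
    r2 = fit$r2, r2_adj = fit$r2_adj,
    slope = fit$slope, intercept = fit$intercept, prefactor = fit$prefactor,
    scales_mm = fit$curve$scales_mm, mean_counts = fit$curve$mean_counts,
    n_offsets = fit$n_offsets, seed = fit$seed, version = fit$version
  )
}

#' @rdname fd_report
#' @param path JSON file path.
#' @export
write_fd_report <- function(fit, path) {
  # I(17) = 17 significant digits, the shortest representation that
  # round-trips every double exactly
  jsonlite::write_json(fd_report(fit), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname fd_report
#' @export
read_fd_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Batch FD estimation over masks and strategies
#'
#' Runs [fd_fit()] for every combination of input volume and strategy.
#' Per-subject seeds are derived deterministically from the master seed
#' and the subject id, so reruns with the same master seed reproduce the
#' table exactly and results do not depend on processing order.  Failures
#' (unreadable files, empty masks, degenerate intervals) are recorded in
#' the `error` column, never fatal.
#'
#' @param x character vector of NIfTI paths, or a named list of
#'   [voxel_volume]s.
#' @param strategies strategies to apply (default: all four).
#' @param scales,n_offsets,seed as in [fd_fit()]; `seed` is the master
#'   seed.
#' @param ... passed to [fd_fit()].
#' @return A `data.frame` with columns `subject_id`, `strategy`, `fd`,
#'   `mfs_mm`, `Mfs_mm`, `width_decades`, `r2_adj`, `error`.
#' @export
fd_batch <- function(x, strategies = c("fixed", "bbox", "maxr2", "roundedr2"),
                     scales = default_scales(), n_offsets = 20, seed = 1,
                     ...) {
  if (is.character(x)) {
    ids <- ifelse(nzchar(names2(x)), names2(x),
                  sub("\\.nii(\\.gz)?$", "", basename(x)))
    getter <- function(i) read_mask(x[i])
  } else if (is.list(x)) {
    ids <- if (is.null(names(x))) sprintf("sub-%04d", seq_along(x)) else names(x)
    getter <- function(i) x[[i]]
  } else stop("InvalidInput: x must be file paths or a list of volumes")

  rows <- list()
  for (i in seq_along(ids)) {
    sid <- ids[i]
    sseed <- subject_seed(seed, sid)
    vol <- tryCatch(getter(i), error = function(e) e)
    for (st in strategies) {
      row <- data.frame(subject_id = sid, strategy = st, fd = NA_real_,
                        mfs_mm = NA_real_, Mfs_mm = NA_real_,
                        width_decades = NA_real_, r2_adj = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      if (inherits(vol, "error")) {
        row$error <- conditionMessage(vol)
      } else {
        fit <- tryCatch(
          fd_fit(vol, strategy = st, scales = scales,
                 n_offsets = n_offsets, seed = sseed,
                 subject_id = sid, ...),
          error = function(e) e)
        if (inherits(fit, "error")) {
          row$error <- conditionMessage(fit)
        } else {
          row$fd <- fit$fd; row$mfs_mm <- fit$mfs; row$Mfs_mm <- fit$Mfs
          row$width_decades <- fit$width_decades; row$r2_adj <- fit$r2_adj
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

names2 <- function(x) if (is.null(names(x))) rep("", length(x)) else names(x)
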