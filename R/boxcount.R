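#' Default dyadic scale set
#'
#' Box sides sampled uniformly in log space: s = 2^k voxels for
#' k = 0, ..., `max_k`.  With 1 mm isotropic voxels these are the scales
#' 1-256 mm typically used for whole-brain cortical masks.  Scales larger
#' than the volume are allowed; their counts saturate near 1 and the
#' scale-selection stage decides whether to use them.
#'
#' @param max_k largest exponent (default 8, i.e. scales 1..256).
#' @return Integer vector of box sides in voxels, strictly increasing.
#' @export
default_scales <- function(max_k = 8) {
  stopifnot(max_k >= 0)
  as.integer(2^(0:max_k))
}

#' Count occupied boxes for one grid placement
#'
#' Superimposes a grid of cubic boxes of side `s` voxels, with its origin
#' shifted by an integer `offset`, and counts the number of distinct cells
#' containing at least one foreground voxel.  Voxel v (0-based) maps to
#' cell `floor((v + offset) / s)`; the grid conceptually extends beyond
#' the volume so no voxel is ever lost.
#'
#' @param vol a [voxel_volume] with nonempty foreground.
#' @param s box side in voxels (`>= 1`).
#' @param offset integer triple, each component in `[0, s)`.
#' @return Integer box count, between 1 and the foreground voxel count.
#' @examples
#' box_count(phantom_cube(8), s = 2)  # 64
#' @export
box_count <- function(vol, s, offset = c(0L, 0L, 0L)) {
  stopifnot(inherits(vol, "voxel_volume"))
  coords <- fg_coords(vol)
  check_offset(offset, s)
  count_cells(coords, s, offset)
}

# 0-based foreground coordinates, computed once per volume and reused.
fg_coords <- function(vol) {
  idx <- which(vol$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("EmptyVolume: no foreground voxels")
  idx - 1L
}

check_offset <- function(offset, s) {
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != round(s))
    stop("InvalidScale: s must be a positive integer")
  if (length(offset) != 3L || any(offset < 0) || any(offset >= s) ||
      any(offset != round(offset)))
    stop("OffsetOutOfRange: offset components must be integers in [0, s)")
  invisible(TRUE)
}

# Core counter: pack cell indices into one number and count unique values.
# Doubles are exact here (cell ids far below 2^53).
count_cells <- function(coords, s, offset) {
  cx <- (coords[, 1L] + offset[1L]) %/% s
  cy <- (coords[, 2L] + offset[2L]) %/% s
  cz <- (coords[, 3L] + offset[3L]) %/% s
  k1 <- max(cx) + 1
  k2 <- max(cy) + 1
  length(unique(cx + k1 * (cy + k2 * cz)))
}

#' Box-count curve across scales with offset averaging
#'
#' For each scale s, counts occupied boxes and, when `n_offsets > 0`,
#' averages the counts over `n_offsets` grid origins drawn uniformly and
#' independently from the integer offsets {0, ..., s-1}^3.  Offset
#' averaging removes the systematic influence of grid placement on the
#' count.  With `n_offsets = 0` a single grid aligned to the volume origin
#' is used and the counts are exact integers (the deterministic mode used
#' by analytic phantom tests).
#'
#' Each scale draws its offsets from its own RNG substream derived from
#' `seed`, so adding or removing scales never perturbs the draws of the
#' others, and the curve is bit-reproducible from `(vol, scales,
#' n_offsets, seed)`.
#'
#' @param vol a [voxel_volume] with nonempty foreground.
#' @param scales strictly increasing integer box sides in voxels.
#' @param n_offsets number of random grid origins per scale (default 20;
#'   0 = aligned deterministic mode).
#' @param seed master RNG seed for the offset draws.
#' @param keep_offsets also store the per-offset integer counts.
#' @return An object of class `fd_curve`: a list with `scales` (voxels),
#'   `scales_mm`, `mean_counts`, `n_offsets`, `seed`, `spacing`,
#'   `n_foreground` and optionally `per_offset_counts` (matrix, offsets x
#'   scales).
#' @examples
#' crv <- fd_boxcount(phantom_cube(16), scales = c(1, 2, 4, 8), n_offsets = 0)
#' crv$mean_counts  # (16/s)^3
#' @export
fd_boxcount <- function(vol, scales = default_scales(), n_offsets = 20,
                        seed = 1, keep_offsets = FALSE) {
  stopifnot(inherits(vol, "voxel_volume"))
  scales <- as.integer(scales)
  if (length(scales) < 1L || any(scales < 1L) || is.unsorted(scales, strictly = TRUE))
    stop("InvalidScale: scales must be strictly increasing integers >= 1")
  if (n_offsets < 0 || n_offsets != round(n_offsets))
    stop("InvalidParams: n_offsets must be a non-negative integer")
  coords <- fg_coords(vol)
  nfg <- nrow(coords)

  per <- if (keep_offsets && n_offsets > 0)
    matrix(NA_integer_, nrow = n_offsets, ncol = length(scales)) else NULL
  means <- numeric(length(scales))
  for (k in seq_along(scales)) {
    s <- scales[k]
    if (n_offsets == 0L) {
      means[k] <- count_cells(coords, s, c(0, 0, 0))
    } else {
      offs <- with_seed(substream_seed(seed, k), {
        matrix(sample.int(s, 3L * n_offsets, replace = TRUE) - 1L,
               ncol = 3L)
      })
      cnts <- vapply(seq_len(n_offsets), function(i)
        count_cells(coords, s, offs[i, ]), numeric(1))
      means[k] <- mean(cnts)
      if (!is.null(per)) per[, k] <- as.integer(cnts)
    }
  }
  structure(
    list(scales = scales,
         scales_mm = scales * vol$spacing[1L],
         mean_counts = means,
         n_offsets = as.integer(n_offsets),
         seed = seed,
         spacing = vol$spacing[1L],
         n_foreground = nfg,
         per_offset_counts = per),
    class = "fd_curve"
  )
}

#' @export
print.fd_curve <- function(x, ...) {
  cat("fd_curve:", length(x$scales), "scales,",
      x$n_offsets, "offsets per scale\n")
  print(data.frame(s_voxels = x$scales, s_mm = x$scales_mm,
                   mean_N = x$mean_counts))
  invisible(x)
}

#' @export
plot.fd_curve <- function(x, ...) {
  graphics::plot(log10(x$scales_mm), log10(x$mean_counts),
                 xlab = "log10 s (mm)", ylab = "log10 N(s)",
                 pch = 19, ...)
  invisible(x)
}
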