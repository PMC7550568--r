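#' Phantom volumes with known dimension
#'
#' Geometric oracle objects for validating the box-counting estimator: a
#' solid cube (dimension 3), a one-voxel-thick plane (dimension 2), a
#' Menger sponge (dimension log 20 / log 3, approximately 2.7268) and a
#' thin perturbed spherical shell, a cortex-like folded surface used for
#' smoke tests.  Cube and plane follow exact power laws on aligned dyadic
#' grids, so the estimator must recover their dimension to machine
#' precision in zero-offset mode.
#'
#' @param side edge length in voxels (`side >= 2`; powers of two give exact
#'   aligned counts).
#' @param spacing isotropic voxel size in mm.
#' @return A [voxel_volume].
#' @examples
#' sum(phantom_menger(2)$data)  # 400 = 20^2
#' @name phantoms
NULL

#' @rdname phantoms
#' @export
phantom_cube <- function(side, spacing = 1) {
  if (!is.numeric(side) || side < 2 || side != round(side))
    stop("InvalidSize: side must be an integer >= 2")
  voxel_volume(array(1L, c(side, side, side)), spacing = spacing)
}

#' @rdname phantoms
#' @export
phantom_plane <- function(side, spacing = 1) {
  if (!is.numeric(side) || side < 2 || side != round(side))
    stop("InvalidSize: side must be an integer >= 2")
  a <- array(0L, c(side, side, side))
  a[, , 1L] <- 1L
  voxel_volume(a, spacing = spacing)
}

#' @rdname phantoms
#' @param level Menger recursion level, 1 to 5; the volume has side
#'   `3^level` voxels and exactly `20^level` foreground voxels.
#' @details The Menger sponge is built with a base-3 digit test: a voxel at
#'   0-based coordinates (x, y, z) is removed iff at some digit position at
#'   least two of its three base-3 digits equal 1.  This is equivalent to
#'   the recursive remove-the-7-centre-subcubes construction but runs in
#'   O(volume) with no recursion.
#' @export
phantom_menger <- function(level, spacing = 1) {
  if (!is.numeric(level) || level != round(level) || level < 1 || level > 5)
    stop("LevelOutOfRange: level must be an integer in [1, 5]")
  side <- 3L^level
  keep <- array(TRUE, c(side, side, side))
  coord <- 0:(side - 1L)
  for (j in seq_len(level)) {
    b <- (coord %/% 3L^(j - 1L)) %% 3L == 1L  # digit j equals 1?
    n1 <- outer(outer(b, b, `+`), b, `+`)     # how many of x,y,z digits are 1
    keep <- keep & (n1 < 2)
  }
  voxel_volume(array(as.integer(keep), dim(keep)), spacing = spacing)
}

#' @rdname phantoms
#' @param radius shell radius in voxels (`>= 8`).
#' @param amplitude radial perturbation amplitude in voxels; 0 gives a
#'   smooth sphere surface (dimension 2).
#' @param seed RNG seed controlling the perturbation harmonics; the same
#'   seed always yields the identical volume.
#' @details The shell is the set of voxels within half a voxel of a radius
#'   field r(theta, phi) = radius + amplitude * sum of three seeded
#'   sinusoidal harmonics on the sphere.  The harmonics span several
#'   angular frequencies, giving deterministic multi-scale roughness
#'   without any noise texture.
#' @export
phantom_shell <- function(radius, amplitude = 0, seed = 1, spacing = 1) {
  if (!is.numeric(radius) || radius < 8)
    stop("InvalidRadius: radius must be >= 8 voxels")
  half <- ceiling(radius + abs(amplitude) + 2)
  side <- 2L * half + 1L
  ctr <- half + 1L
  # octave-spaced angular frequencies with mildly decaying amplitudes:
  # roughness present across spatial scales, not just a long-wave bump
  harm <- with_seed(seed, {
    f <- round(stats::runif(1, 4, 7) * 4^(0:2))
    list(a = f^(-0.3), f = f, g = f,
         p = stats::runif(3, 0, 2 * pi),
         q = stats::runif(3, 0, 2 * pi))
  })
  d <- seq_len(side) - ctr
  dx <- array(d, c(side, side, side))
  dy <- aperm(dx, c(2, 1, 3))
  dz <- aperm(dx, c(3, 2, 1))
  r <- sqrt(dx^2 + dy^2 + dz^2)
  theta <- acos(ifelse(r > 0, dz / pmax(r, 1e-12), 1))
  phi <- atan2(dy, dx)
  pert <- 0
  for (h in 1:3)
    pert <- pert + harm$a[h] * sin(harm$f[h] * theta + harm$p[h]) *
      sin(harm$g[h] * phi + harm$q[h])
  pert <- pert / sum(harm$a)                 # normalize to [-1, 1]
  # digital level set of F = r - r_target: a voxel is on the shell if F
  # changes sign towards any face neighbour (or is within half a voxel of
  # zero).  A plain |F| <= 0.5 band tears wherever the perturbed surface
  # moves faster than one voxel per step; the crossing test keeps the
  # shell watertight at any amplitude.
  F <- r - (radius + amplitude * pert)
  pos <- F > 0
  crosses <- array(FALSE, dim(F))
  n <- side
  crosses[-n, , ] <- crosses[-n, , ] | (pos[-n, , ] != pos[-1, , ])
  crosses[-1, , ] <- crosses[-1, , ] | (pos[-1, , ] != pos[-n, , ])
  crosses[, -n, ] <- crosses[, -n, ] | (pos[, -n, ] != pos[, -1, ])
  crosses[, -1, ] <- crosses[, -1, ] | (pos[, -1, ] != pos[, -n, ])
  crosses[, , -n] <- crosses[, , -n] | (pos[, , -n] != pos[, , -1])
  crosses[, , -1] <- crosses[, , -1] | (pos[, , -1] != pos[, , -n])
  mask <- crosses | abs(F) <= 0.5
  voxel_volume(array(as.integer(mask), dim(mask)), spacing = spacing)
}

#' Simulate a cohort with an age-dependent morphometric feature
#'
#' Generates the synthetic analogue of a brain-morphometry cohort: ages
#' uniform over `age_range`, one feature following a linear age trend with
#' Gaussian noise, sex as Bernoulli(0.5) coded 0/1, and eTIV (estimated
#' total intracranial volume) as Gaussian in mm^3.  Defaults emulate an
#' adult lifespan cohort whose feature is a cortical fractal dimension
#' declining slowly with age.
#'
#' @param n number of subjects (`>= 10`).
#' @param age_range length-2 numeric, years.
#' @param slope feature change per year of age.
#' @param intercept feature value extrapolated to age 0.
#' @param noise_sd residual standard deviation of the feature (`>= 0`).
#' @param feature name of the feature column (default `"FD"`).
#' @param etiv_mean,etiv_sd eTIV distribution parameters in mm^3.
#' @param seed RNG seed; the same seed reproduces the table exactly.
#' @return A `data.frame` with columns `subject_id`, `age`, `sex`, `eTIV`
#'   and the feature column.
#' @examples
#' head(simulate_cohort(n = 20, seed = 1))
#' @export
simulate_cohort <- function(n = 86, age_range = c(19, 85),
                            slope = -7.4e-4, intercept = 2.52,
                            noise_sd = 0.014, feature = "FD",
                            etiv_mean = 1.5e6, etiv_sd = 1.5e5,
                            seed = 1) {
  if (n < 10) stop("InvalidParams: n must be >= 10")
  if (noise_sd < 0) stop("InvalidParams: noise_sd must be >= 0")
  if (length(age_range) != 2 || diff(age_range) <= 0 || any(age_range <= 0))
    stop("InvalidParams: age_range must be increasing and positive")
  with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    feat <- intercept + slope * age + stats::rnorm(n, 0, noise_sd)
    sex <- stats::rbinom(n, 1, 0.5)
    etiv <- stats::rnorm(n, etiv_mean, etiv_sd)
    df <- data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      age = age, sex = sex, eTIV = etiv,
      stringsAsFactors = FALSE
    )
    df[[feature]] <- feat
    validate_cohort(df, c("subject_id", "age", "sex", "eTIV", feature))
  })
}
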