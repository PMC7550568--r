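test_that("log-log fit recovers exact power laws and closed-form OLS", {
  cube <- make_curve((64 / 2^(0:5))^3)
  f <- fit_loglog(cube, 1:6)
  expect_equal(f$fd, 3, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(f$r2_adj, 1)

  plane <- make_curve((64 / 2^(0:5))^2)
  expect_equal(fit_loglog(plane, 1:6)$fd, 2, tolerance = 1e-12)

  # arbitrary 5-point curve against the closed-form OLS oracle
  crv <- make_curve(c(5000, 1600, 420, 130, 40))
  f <- fit_loglog(crv, 1:5)
  o <- oracle_ols(log10(crv$scales_mm), log10(crv$mean_counts))
  expect_equal(f$slope, o$slope, tolerance = 1e-12)
  expect_equal(f$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(f$r2, o$r2, tolerance = 1e-12)
  expect_equal(f$r2_adj, o$r2_adj, tolerance = 1e-12)
  expect_equal(f$fd, abs(f$slope))

  expect_error(fit_loglog(crv, 1:9), "IntervalOutOfRange")
  expect_error(fit_loglog(crv, 3), "IntervalOutOfRange")
})

test_that("fd is invariant to the logarithm base used on both axes", {
  crv <- random_curve(31)
  f10 <- fit_loglog(crv, 2:8)
  idx <- 2:8
  fe <- oracle_ols(log(crv$scales_mm[idx]), log(crv$mean_counts[idx]))
  expect_equal(f10$fd, abs(fe$slope), tolerance = 1e-10)
  expect_equal(f10$r2, fe$r2, tolerance = 1e-10)
})

test_that("interval enumeration is exhaustive and deterministically ordered", {
  crv9 <- make_curve(10^(8 - 2.5 * log10(2^(0:8))))
  expect_length(enumerate_intervals(crv9, min_points = 5), 15)
  expect_length(enumerate_intervals(crv9, min_points = 4), 21)
  crv5 <- make_curve(c(100, 50, 25, 12, 6))
  expect_length(enumerate_intervals(crv5, min_points = 5), 1)
  expect_error(enumerate_intervals(crv5, min_points = 6), "TooFewScales")

  ivs <- enumerate_intervals(crv5, min_points = 2)
  starts <- vapply(ivs, function(x) x$indices[1], numeric(1))
  expect_true(!is.unsorted(starts))
})

test_that("interval width in decades matches the printed convention", {
  expect_equal(round(width_decades(1, 8), 1), 0.9)
  expect_equal(round(width_decades(1, 16), 1), 1.2)
  expect_equal(round(width_decades(1, 32), 1), 1.5)
  expect_equal(width_decades(1, 32), log10(32), tolerance = 1e-12)
  expect_error(width_decades(4, 4), "InvalidBounds")
  expect_error(width_decades(0, 8), "InvalidBounds")
})

test_that("fixed a-priori interval spans the sampled scales in [mfs, Mfs]", {
  crv <- make_curve(10^(8 - 2.5 * log10(2^(0:8))))
  sel <- select_scales(crv, "fixed")  # default [4, 256] mm
  expect_equal(sel$interval$indices, 3:9)
  expect_equal(sel$interval$n_points, 7)
  sel2 <- select_scales(crv, "fixed", mfs = 1, Mfs = 8)
  expect_equal(sel2$interval$n_points, 4)
  expect_error(select_scales(crv, "fixed", mfs = 4, Mfs = 512),
               "BoundsNotSampled")
  expect_error(select_scales(crv, "fixed", mfs = 3, Mfs = 256),
               "BoundsNotSampled")
})

test_that("bounding-box interval uses 5-40% of the shortest side, power-2 rounded", {
  crv <- make_curve(10^(8 - 2.5 * log10(2^(0:8))))
  # shortest bounding-box side 140 mm -> 7 and 56 -> mfs 8, Mfs 64
  vol140 <- voxel_volume(array(1, c(140, 150, 160)))
  sel <- select_scales(crv, "bbox", vol = vol140)
  expect_equal(sel$interval$mfs, 8)
  expect_equal(sel$interval$Mfs, 64)
  # 100 mm -> 5 and 40 -> mfs 4, Mfs 32
  vol100 <- voxel_volume(array(1, c(100, 120, 110)))
  sel <- select_scales(crv, "bbox", vol = vol100)
  expect_equal(sel$interval$mfs, 4)
  expect_equal(sel$interval$Mfs, 32)
  # 160 mm -> 8 and 64 are exact powers, unchanged
  vol160 <- voxel_volume(array(1, c(160, 170, 180)))
  sel <- select_scales(crv, "bbox", vol = vol160)
  expect_equal(sel$interval$mfs, 8)
  expect_equal(sel$interval$Mfs, 64)
  # "next" rounding takes the power of 2 at or above
  sel <- select_scales(crv, "bbox", vol = vol140, rounding = "next")
  expect_equal(sel$interval$mfs, 8)   # 7 -> 8
  expect_equal(sel$interval$Mfs, 64)  # 56 -> 64
  # the bounding box is of the foreground, not the array
  pad <- array(0, c(200, 200, 200))
  pad[30 + 1:100, 20 + 1:120, 40 + 1:110] <- 1
  sel <- select_scales(crv, "bbox", vol = voxel_volume(pad))
  expect_equal(sel$interval$mfs, 4)
  expect_equal(sel$interval$Mfs, 32)
  # a one-voxel slab: 5-40% of a 1 mm side falls below every sampled scale
  expect_error(select_scales(crv, "bbox", vol = phantom_plane(16)),
               "DegenerateInterval")
})

test_that("automated strategies match the brute-force enumerate-fit-rank oracle", {
  for (seed in 1:200) {
    crv <- random_curve(seed)
    a <- select_scales(crv, "maxr2")
    oa <- oracle_select(crv$scales_mm, crv$mean_counts, 4, "maxr2")
    expect_equal(range(a$interval$indices), c(oa$i, oa$j),
                 info = paste("maxr2 seed", seed))
    b <- select_scales(crv, "roundedr2")
    ob <- oracle_select(crv$scales_mm, crv$mean_counts, 5, "roundedr2")
    expect_equal(range(b$interval$indices), c(ob$i, ob$j),
                 info = paste("roundedr2 seed", seed))
    # default 9-scale set, min 5 points: any candidate spans >= log10(16)
    expect_gte(b$interval$width_decades, log10(16) - 1e-12)
  }
})

test_that("exact power laws trigger the documented tie-breaks", {
  crv <- make_curve(10^(8 - 2.7 * log10(2^(0:8))))
  # every window fits perfectly; maxr2 keeps the first enumerated window
  a <- select_scales(crv, "maxr2")
  expect_equal(a$interval$indices, 1:4)
  # roundedr2 prefers the widest window: all 9 scales, [1, 256] mm
  b <- select_scales(crv, "roundedr2")
  expect_equal(b$interval$indices, 1:9)
  expect_equal(b$interval$mfs, 1)
  expect_equal(b$interval$Mfs, 256)
})

test_that("rounded ranking separates effective from non-effective decimals", {
  # roughness small enough that every window rounds to 1.000:
  # the widest window wins even if a narrow one has higher unrounded r2_adj
  lx <- log10(2^(0:8))
  wig <- 0.004 * sin(1:9)
  near <- make_curve(10^(7 - 2.6 * lx + wig))
  rr <- vapply(enumerate_intervals(near, 5), function(iv)
    oracle_round_half_up(fit_loglog(near, iv)$r2_adj, 3), numeric(1))
  expect_true(all(rr == 1))  # fixture precondition
  sel <- select_scales(near, "roundedr2")
  expect_equal(sel$interval$indices, 1:9)

  # a bent tail lowers wide-window rounded r2_adj below a clean 5-point
  # window: the narrower window must win
  ly <- 9 - 3 * lx
  ly[6:9] <- ly[5] - 1.0 * (lx[6:9] - lx[5])
  bent <- make_curve(10^ly)
  fits <- lapply(enumerate_intervals(bent, 5), function(iv) fit_loglog(bent, iv))
  rr <- vapply(fits, function(f) oracle_round_half_up(f$r2_adj, 3), numeric(1))
  widths <- vapply(fits, function(f) f$interval$width_decades, numeric(1))
  expect_lt(max(rr[widths > log10(16) + 1e-9]), 1)  # precondition: wide windows impaired
  sel <- select_scales(bent, "roundedr2")
  expect_equal(sel$interval$indices, 1:5)
  expect_equal(sel$fit$fd, 3, tolerance = 1e-9)
})

test_that("half-away-from-zero rounding is used for r2_adj ranking", {
  expect_equal(fracdim3d:::round_half_up(0.9995, 3), 1)
  expect_equal(fracdim3d:::round_half_up(0.99849, 3), 0.998)
  expect_equal(fracdim3d:::round_half_up(-0.0005, 3), -0.001)
})
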