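# analytic dose fixtures on a 20 x 50 x 100 mm box (100 cm^3); the gradient
# fixture uses 0.25 mm z-sampling so dose quantization stays below the DVH
# bin width
make_box_dose <- function(fill, zsp = 1) {
  g <- grid_spec(c(0, 0, 0), c(1, 1, zsp), c(20, 50, round(100 / zsp)))
  mask <- binary_mask(g, array(TRUE, g$shape))
  dose <- dose_grid(g, fill(g))
  list(dose = dose, mask = mask)
}

linear_z <- function(g) {
  # 0 -> 50 Gy along z at voxel centres
  zc <- (seq_len(g$shape[3]) - 0.5) / g$shape[3] * 50
  array(rep(zc, each = g$shape[1] * g$shape[2]), g$shape)
}

test_that("cumulative DVH reproduces analytic shapes", {
  u <- make_box_dose(function(g) array(10, g$shape))
  dvh <- cumulative_dvh(u$dose, u$mask)
  expect_equal(dvh$bin_width, 0.1)
  expect_equal(dvh$total_volume_cc, 100)
  expect_true(all(diff(dvh$volume_cc) <= 0))
  expect_equal(dvh$volume_cc[1], 100)                      # at 0 Gy
  expect_equal(dvh$volume_cc[dvh$dose_gy == 10], 100)      # plateau
  expect_equal(dvh$volume_cc[dvh$dose_gy > 10], 0)         # beyond max

  two <- make_box_dose(function(g) {
    d <- array(2, g$shape); d[, , 51:100] <- 40; d
  })
  dvh2 <- cumulative_dvh(two$dose, two$mask)
  expect_equal(dvh2$volume_cc[dvh2$dose_gy == 10], 50)     # 50% plateau
  expect_equal(dvh2$volume_cc[dvh2$dose_gy == 2], 100)

  lin <- make_box_dose(linear_z, zsp = 0.25)
  dvhl <- cumulative_dvh(lin$dose, lin$mask)
  mid <- dvhl$volume_cc[dvhl$dose_gy == 25]
  expect_equal(mid, 50, tolerance = 0.01)                  # straight line
  expect_equal(dvhl$volume_cc[dvhl$dose_gy == 40], 20, tolerance = 0.01)
})

test_that("DMEAN is the voxel mean", {
  u <- make_box_dose(function(g) array(10, g$shape))
  expect_equal(dmean(u$dose, u$mask), 10)
  lin <- make_box_dose(linear_z, zsp = 0.25)
  expect_equal(dmean(lin$dose, lin$mask), 25, tolerance = 1e-9)
  two <- make_box_dose(function(g) {
    d <- array(2, g$shape); d[, , 51:100] <- 40; d
  })
  expect_equal(dmean(two$dose, two$mask), 21)
})

test_that("D2CC interpolates the cumulative DVH", {
  u <- make_box_dose(function(g) array(10, g$shape))
  expect_equal(as.numeric(d2cc(cumulative_dvh(u$dose, u$mask))), 10,
               tolerance = 0.1)

  lin <- make_box_dose(linear_z, zsp = 0.25)
  d49 <- as.numeric(d2cc(cumulative_dvh(lin$dose, lin$mask)))
  expect_lte(abs(d49 - 49), 0.1)

  # exactly 2 cm^3 at uniform dose -> that dose
  g <- grid_spec(c(0, 0, 0), 1, c(20, 10, 10))
  m <- binary_mask(g, array(TRUE, g$shape))
  dv <- cumulative_dvh(dose_grid(g, array(7.3, g$shape)), m)
  expect_equal(dv$total_volume_cc, 2)
  expect_equal(as.numeric(d2cc(dv)), 7.3, tolerance = 1e-9)

  # sub-2cc structure: flagged, minimum dose returned
  gs <- grid_spec(c(0, 0, 0), 1, c(10, 10, 10))
  ms <- binary_mask(gs, array(TRUE, gs$shape))
  dvs <- cumulative_dvh(dose_grid(gs, array(4.2, gs$shape)), ms)
  d2s <- d2cc(dvs)
  expect_equal(attr(d2s, "flag"), "volume<2cc")
  expect_equal(as.numeric(d2s), 4.2, tolerance = 0.1)

  # bin-floor variant: never above the interpolated value, within one bin
  dfl <- as.numeric(d2cc(cumulative_dvh(lin$dose, lin$mask),
                         interpolate = FALSE))
  expect_lte(dfl, d49)
  expect_lte(d49 - dfl, 0.1)
})

test_that("V5GY is the fraction at or above 5 Gy", {
  u <- make_box_dose(function(g) array(10, g$shape))
  expect_equal(v5gy(cumulative_dvh(u$dose, u$mask)), 1)
  lo <- make_box_dose(function(g) array(2, g$shape))
  expect_equal(v5gy(cumulative_dvh(lo$dose, lo$mask)), 0)
  lin <- make_box_dose(linear_z, zsp = 0.25)
  expect_equal(v5gy(cumulative_dvh(lin$dose, lin$mask)), 0.90,
               tolerance = 0.002)
})

test_that("DVH-integrated mean agrees with the grid mean within a bin", {
  lin <- make_box_dose(linear_z, zsp = 0.25)
  dvh <- cumulative_dvh(lin$dose, lin$mask)
  # trapezoidal integral of the (normalized) cumulative DVH = mean dose
  rel <- dvh$volume_cc / dvh$total_volume_cc
  dv <- diff(dvh$dose_gy)
  dvh_mean <- sum((head(rel, -1) + rel[-1]) / 2 * dv)
  expect_equal(dvh_mean, dmean(lin$dose, lin$mask), tolerance = 0.1)
})

test_that("D2CC scales linearly with a uniform dose rescaling", {
  lin <- make_box_dose(linear_z, zsp = 0.25)
  d1 <- as.numeric(d2cc(cumulative_dvh(lin$dose, lin$mask)))
  half <- dose_grid(lin$dose$grid, lin$dose$dose * 0.5)
  d2 <- as.numeric(d2cc(cumulative_dvh(half, lin$mask)))
  expect_lte(d2, d1)
  expect_equal(d2, d1 / 2, tolerance = 0.01)
})

test_that("metrics are invariant to translating grid and mask together", {
  lin <- make_box_dose(linear_z, zsp = 0.25)
  g2 <- grid_spec(c(100, -40, 7), lin$dose$grid$spacing,
                  lin$dose$grid$shape)
  dose2 <- dose_grid(g2, lin$dose$dose)
  mask2 <- binary_mask(g2, lin$mask$values)
  expect_equal(dmean(dose2, mask2), dmean(lin$dose, lin$mask))
  expect_equal(as.numeric(d2cc(cumulative_dvh(dose2, mask2))),
               as.numeric(d2cc(cumulative_dvh(lin$dose, lin$mask))))
})

test_that("degenerate dosimetry inputs error clearly", {
  g <- grid_spec(c(0, 0, 0), 1, c(5, 5, 5))
  d <- dose_grid(g, array(1, g$shape))
  empty <- binary_mask(g, array(FALSE, g$shape))
  expect_error(cumulative_dvh(d, empty), "empty")
  expect_error(dmean(d, empty), "empty")
  g2 <- grid_spec(c(1, 0, 0), 1, c(5, 5, 5))
  expect_error(dmean(d, binary_mask(g2, array(TRUE, g2$shape))),
               "different grids")
  expect_error(dose_grid(g, array(-1, g$shape)), "non-negative")
})
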