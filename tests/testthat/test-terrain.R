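test_that("ASCII grid read-back is the identity, honours nodata and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 0.02", "NODATA_value -9999",
               "1.0 1.0 1.0", "1.0 1.0 1.0", "1.0 1.0 1.0"), tmp)
  g <- read_dem(tmp)
  expect_equal(sum(!is.na(g$values)), 9L)
  expect_equal(g$cell_size, 0.02)
  expect_true(all(g$values == 1))

  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 0.02", "NODATA_value -9999",
               "1.0 1.0 1.0", "1.0 -9999 1.0", "1.0 1.0 1.0"), tmp)
  g2 <- read_dem(tmp)
  expect_true(is.na(g2$values[2, 2]))
  expect_equal(sum(!is.na(g2$values)), 8L)

  set.seed(42)
  g3 <- elevation_grid(matrix(rnorm(256), 16, 16), 0.05, origin = c(10, 20))
  write_ascii_grid(g3, tmp)
  back <- read_dem(tmp)
  expect_equal(back$values, g3$values, tolerance = 1e-9)
  expect_equal(back$cell_size, g3$cell_size)
  expect_equal(back$origin, g3$origin)
})

test_that("degenerate elevation inputs are rejected", {
  expect_error(elevation_grid(matrix(NA_real_, 3, 3), 0.02), "nodata")
  expect_error(elevation_grid(matrix(1, 3, 3), -1), "cell_size")
  expect_error(compute_slope_aspect(elevation_grid(matrix(1, 2, 5), 1)),
               "3x3")
})

test_that("slope/aspect of analytic planes match closed-form gradients", {
  # horizontal plane
  flat <- synthetic_dem("plane", shape = c(9, 9), base = 2)
  d <- compute_slope_aspect(flat)
  expect_true(all(d$slope[2:8, 2:8] == 0))
  expect_true(all(d$aspect[2:8, 2:8] == 0))

  # descending toward north at 0.1 m/m: north-facing downslope
  north <- synthetic_dem("plane", shape = c(9, 9), base = 5, slope_y = -0.1)
  dn <- compute_slope_aspect(north)
  expect_equal(dn$slope[5, 5], atan(0.1) * 180 / pi, tolerance = 0.01)
  expect_equal(dn$aspect[5, 5], 0, tolerance = 0.01)

  # descending toward east at 1.0 m/m: 45 degrees, aspect 90
  east <- synthetic_dem("plane", shape = c(9, 9), base = 5, slope_x = -1)
  de <- compute_slope_aspect(east)
  expect_equal(de$slope[5, 5], 45, tolerance = 0.01)
  expect_equal(de$aspect[5, 5], 90, tolerance = 0.01)

  # border cells are masked, not extrapolated
  expect_true(all(is.na(d$slope[1, ])))
  expect_true(all(is.na(d$slope[, 9])))
})

test_that("horizon angles: flat plane, wall geometry, brute-force oracle", {
  flat <- synthetic_dem("plane", shape = c(11, 11), cell_size = 0.1, base = 0)
  d <- compute_horizon_angles(flat, n_directions = 8, max_radius = 0.4)
  # interior cells see no horizon in any direction
  expect_true(all(d$horizon_angles[4:8, 4:8, ] == 0))

  # wall of height h east of the cell: angle atan(h/d) toward the wall
  h <- 0.5
  wall <- synthetic_dem("step", shape = c(9, 12), cell_size = 0.1,
                        base = 0, amplitude = h)
  dw <- compute_horizon_angles(wall, n_directions = 4, max_radius = 1.0)
  # wall occupies columns 7..12; direction index 2 is azimuth 90 (east)
  for (j in c(3, 5)) {
    dist <- (7 - j) * 0.1
    expect_equal(dw$horizon_angles[5, j, 2], atan(h / dist) * 180 / pi,
                 tolerance = 1e-6)
  }
  # away from the wall (west, index 4) the plane is flat
  expect_equal(dw$horizon_angles[5, 5, 4], 0)

  # random rugged DEM vs an independent per-pixel scan at the same step:
  # exact agreement (same discretisation, different code path)
  g <- synthetic_dem("gaussian_field", shape = c(12, 12), cell_size = 0.1,
                     target_rq = 0.2, spectral_exponent = -3, seed = 7)
  dg <- compute_horizon_angles(g, n_directions = 8, max_radius = 0.6)
  orc_same <- oracle_horizon(g$values, 0.1, 8, 0.6, step_frac = 1)
  expect_equal(dg$horizon_angles, orc_same, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gt(max(orc_same), 20)  # the field is not trivial

  # gentle DEM vs 4x finer ray sampling beyond the first cell (the first
  # cell is below the one-cell-step resolution by construction)
  gs <- synthetic_dem("gaussian_field", shape = c(12, 12), cell_size = 0.1,
                      target_rq = 0.02, spectral_exponent = -3, seed = 7)
  dgs <- compute_horizon_angles(gs, n_directions = 8, max_radius = 0.6)
  orc_fine <- oracle_horizon(gs$values, 0.1, 8, 0.6, step_frac = 0.25,
                             start_frac = 1)
  err <- abs(dgs$horizon_angles - orc_fine)
  expect_lt(quantile(err, 0.99), 2)            # bulk of cells within 2 deg
  expect_lt(max(err), 0.2 * max(orc_fine))     # worst case bounded by relief
})

test_that("SVF closed forms and monotonicity", {
  d <- list(horizon_angles = array(0, c(2, 2, 8)))
  class(d) <- "terrain_derivatives"
  expect_equal(compute_svf(d)$svf, matrix(1, 2, 2))

  d$horizon_angles[] <- 90
  expect_equal(compute_svf(d)$svf, matrix(0, 2, 2), tolerance = 1e-12)

  d$horizon_angles[] <- rep(c(0, 90), each = 2 * 2 * 4)
  expect_equal(compute_svf(d)$svf, matrix(0.5, 2, 2), tolerance = 1e-12)

  d$horizon_angles[] <- 45
  expect_equal(compute_svf(d)$svf, matrix(0.5, 2, 2), tolerance = 1e-12)

  # raising any one horizon angle never raises SVF
  set.seed(11)
  h <- array(runif(3 * 3 * 8, 0, 80), c(3, 3, 8))
  d$horizon_angles <- h
  s0 <- compute_svf(d)$svf
  for (k in 1:8) {
    d2 <- d
    d2$horizon_angles[2, 2, k] <- h[2, 2, k] + 5
    expect_lte(compute_svf(d2)$svf[2, 2], s0[2, 2])
  }

  # SVF bounded on arbitrary terrain
  g <- synthetic_dem("gaussian_field", shape = c(16, 16), target_rq = 0.5,
                     seed = 2)
  svf <- compute_terrain(g, 16, 0.3)$svf
  expect_true(all(svf >= 0 & svf <= 1, na.rm = TRUE))
})

test_that("Rq: planes give zero, sinusoid gives A/sqrt(2), oracle equality,
           translation/tilt invariance", {
  flat <- synthetic_dem("plane", shape = c(10, 10), base = 3)
  expect_lt(surface_roughness_rq(flat), 1e-10)
  tilted <- synthetic_dem("plane", shape = c(10, 10), slope_x = 0.3,
                          slope_y = -0.2)
  expect_lt(surface_roughness_rq(tilted), 1e-10)

  # 20 full periods, 25 samples each: discrete RMS of a sinusoid is exact
  A <- 0.37
  sine <- synthetic_dem("sinusoid", shape = c(5, 500), cell_size = 0.01,
                        amplitude = A, wavelength = 0.25)
  expect_equal(surface_roughness_rq(sine), A / sqrt(2), tolerance = 1e-3)

  set.seed(5)
  z <- matrix(rnorm(400), 20, 20)
  g <- elevation_grid(z, 0.02)
  # direct residual computation
  idx <- which(!is.na(z), arr.ind = TRUE)
  fit <- lm(as.vector(z) ~ I(idx[, "col"] * 0.02) + I(idx[, "row"] * 0.02))
  expect_equal(surface_roughness_rq(g), sqrt(mean(resid(fit)^2)),
               tolerance = 1e-12)

  # invariant to offset and to adding any plane
  g2 <- g; g2$values <- g$values + 11.3
  expect_equal(surface_roughness_rq(g2), surface_roughness_rq(g))
  xy <- expand.grid(r = 1:20, c = 1:20)
  g3 <- g
  g3$values <- g$values + matrix(0.5 * xy$c - 0.2 * xy$r, 20, 20) * 0.02
  expect_equal(surface_roughness_rq(g3), surface_roughness_rq(g),
               tolerance = 1e-9)

  expect_error(surface_roughness_rq(
    elevation_grid(matrix(c(1, 2, NA, NA), 2, 2), 1)), "3 valid")
})

test_that("nodata propagates: masked cells have no derivatives and truncate rays", {
  z <- matrix(0, 9, 9)
  z[5, 5] <- NA
  g <- elevation_grid(z, 0.1)
  d <- compute_terrain(g, 8, 0.4)
  expect_true(is.na(d$slope[5, 5]))
  expect_true(is.na(d$svf[5, 5]))
  expect_true(all(is.na(d$horizon_angles[5, 5, ])))
  # neighbours still get finite SVF (rays truncate rather than fail)
  expect_true(is.finite(d$svf[3, 3]))
})
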