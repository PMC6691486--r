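test_that("RqT/RqP: two-point values, oracle equality, invariances", {
  expect_equal(thermal_roughness(make_temp_field(matrix(c(24, 26), 1, 2))),
               1.0)
  expect_equal(thermal_roughness(make_temp_field(matrix(25, 2, 3))), 0)

  set.seed(9)
  v <- matrix(rnorm(100, 30, 4), 10, 10)
  tf <- make_temp_field(v)
  expect_equal(thermal_roughness(tf), sqrt(mean((v - mean(v))^2)),
               tolerance = 1e-12)

  # translation invariance and scale equivariance
  expect_equal(thermal_roughness(make_temp_field(v + 7)),
               thermal_roughness(tf), tolerance = 1e-9)
  expect_equal(thermal_roughness(make_temp_field(v * 3)),
               3 * thermal_roughness(tf), tolerance = 1e-9)

  # submerged cells are excluded by default, included on request
  ex <- matrix(TRUE, 10, 10); ex[1, ] <- FALSE
  tf2 <- make_temp_field(v, exposure = ex)
  vex <- v[ex]
  expect_equal(thermal_roughness(tf2), sqrt(mean((vex - mean(vex))^2)))
  expect_equal(thermal_roughness(tf2, include_submerged = TRUE),
               thermal_roughness(tf))

  # RqP on a hand-made performance field
  pf <- structure(list(performance = matrix(c(0.4, 0.6), 1, 2),
                       exposure = matrix(TRUE, 1, 2)),
                  class = "performance_field")
  expect_equal(performance_roughness(pf), 0.1)

  expect_error(thermal_roughness(make_temp_field(matrix(25, 1, 1))),
               "2 exposed")
})

test_that("refugia: manual count, edge thresholds, area conservation", {
  v <- matrix(c(25, 27, 29, 31, 26, 33, 28, 24, 35), 3, 3)
  tf <- make_temp_field(v)
  r <- refugia_area(tf, 28, cell_size = 0.02)
  expect_equal(sum(r$refugium_mask), 4L)
  expect_equal(r$refugia_area, 4 * 0.0004)
  expect_equal(r$exposed_area, 9 * 0.0004)
  expect_equal(r$fraction, 4 / 9)

  expect_equal(refugia_area(tf, 20, 0.02)$refugia_area, 0)
  expect_equal(refugia_area(tf, 50, 0.02)$fraction, 1)
  # refugia + complement = exposed exactly
  expect_equal(r$refugia_area + (9 - 4) * 0.0004, r$exposed_area)

  # strictness: a cell exactly at the threshold is not a refugium
  expect_equal(sum(refugia_area(make_temp_field(matrix(28, 2, 2)),
                                28, 1)$refugium_mask), 0L)

  # minimum-patch filter drops isolated cells
  v2 <- matrix(40, 5, 5)
  v2[1, 1] <- 20            # isolated cool cell
  v2[3:4, 3:4] <- 20        # 4-cell cool patch
  tf2 <- make_temp_field(v2)
  r2 <- refugia_area(tf2, 28, 1, min_patch_cells = 2)
  expect_equal(sum(r2$refugium_mask), 4L)
  expect_false(r2$refugium_mask[1, 1])

  expect_error(refugia_area(make_temp_field(matrix(1, 2, 2),
                                            exposure = matrix(FALSE, 2, 2)),
                            28, 1), "exposed")
})

test_that("corridor maps partition category change between hours", {
  tpc <- tpc_preset("generic_intertidal")
  p1 <- performance_field(make_temp_field(matrix(c(25, 25, 40, 40), 2, 2)),
                          tpc)
  p2 <- performance_field(make_temp_field(matrix(c(25, 40, 40, 25), 2, 2)),
                          tpc)
  cr <- corridor_map(p1, p2, "optimal", cell_size = 1)
  expect_equal(sum(cr$persistent), 1L)
  expect_equal(sum(cr$lost), 1L)
  expect_equal(sum(cr$gained), 1L)
  expect_equal(cr$lost_area, 1)
  # persistent and lost partition the t1 mask; no overlap
  m1 <- thermalscape:::category_mask(p1, "optimal")
  expect_equal(cr$persistent | cr$lost, m1)
  expect_false(any(cr$persistent & cr$lost))
  expect_false(any(cr$persistent & cr$gained))
  # union of masks = persistent | lost | gained
  m2 <- thermalscape:::category_mask(p2, "optimal")
  expect_equal(cr$persistent | cr$lost | cr$gained, m1 | m2)

  # identical fields: nothing lost or gained
  cr0 <- corridor_map(p1, p1, "optimal", cell_size = 1)
  expect_equal(sum(cr0$lost) + sum(cr0$gained), 0L)

  # disjoint masks: nothing persists
  p3 <- performance_field(make_temp_field(matrix(c(40, 40, 25, 25), 2, 2)),
                          tpc)
  expect_equal(sum(corridor_map(p1, p3, "optimal", 1)$persistent), 0L)
})

test_that("two-species interaction maps follow survivability", {
  dom <- tpc_preset("generic_predator")      # t_opt 25, lethal 32
  sub <- tpc_preset("generic_intertidal")    # t_opt 28, lethal 35

  cool <- species_interaction_map(make_temp_field(matrix(24, 3, 3)),
                                  dom, sub, cell_size = 1)
  expect_true(all(cool$class == "both"))
  expect_equal(unname(cool$areas["both"]), 9)

  warm <- species_interaction_map(make_temp_field(matrix(33, 3, 3)),
                                  dom, sub, cell_size = 1)
  expect_true(all(warm$class == "prey_only"))

  hot <- species_interaction_map(make_temp_field(matrix(40, 3, 3)),
                                 dom, sub, cell_size = 1)
  expect_true(all(hot$class == "neither"))

  # classes partition the exposed area
  v <- matrix(seq(20, 40, length.out = 16), 4, 4)
  mix <- species_interaction_map(make_temp_field(v), dom, sub, cell_size = 2)
  expect_equal(sum(mix$areas), 16 * 4)
})

test_that("frequency distributions conserve exposed-cell counts", {
  v <- matrix(c(22.5, 23.5, 23.7, 29.2, 41.0), 1, 5)
  h <- frequency_distribution(make_temp_field(v), c(22, 23, 24, 30, 42))
  expect_equal(h$count, c(1L, 2L, 1L, 1L))
  expect_equal(sum(h$count), 5L)

  set.seed(21)
  v2 <- matrix(runif(144, 10, 45), 12, 12)
  ex <- matrix(runif(144) > 0.3, 12, 12)
  tf <- make_temp_field(v2, exposure = ex)
  h2 <- frequency_distribution(tf, seq(10, 45, by = 5))
  expect_equal(sum(h2$count), sum(ex))

  # all values into one bin
  h3 <- frequency_distribution(make_temp_field(matrix(25, 3, 3)),
                               c(20, 30, 40))
  expect_equal(h3$count, c(9L, 0L))

  expect_error(frequency_distribution(tf, c(3, 2, 1)), "increasing")
})

test_that("metrics table is tidy and flags hours without exposed cells", {
  dem <- synthetic_dem("plane", shape = c(5, 5), base = 1, cell_size = 0.1)
  d <- compute_terrain(dem, 8, 0.4)
  times <- utc("2017-06-22 15:00") + 3600 * (0:1)
  weather <- data.frame(timestamp = times, air_temperature = 25,
                        wind_speed = 2, ghi = c(600, 0),
                        water_temperature = 16)
  tide <- data.frame(timestamp = times, level = c(-1, 10))
  fields <- run_simulation(dem, d, weather, tide,
                           heat_budget_params(substrate_temperature = 20),
                           42.508, -70.843)
  expect_warning(
    tab <- landscape_metrics_table(fields, tpc_preset("generic_intertidal"),
                                   0.1, thresholds = 28),
    "fewer than 2 exposed")
  expect_setequal(names(tab), c("timestamp", "metric", "value"))
  # hour 1 has real metrics, flooded hour 2 has NA roughness
  expect_true(is.na(tab$value[tab$metric == "rqt_c"][2]))
  expect_false(is.na(tab$value[tab$metric == "rqt_c"][1]))
})
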