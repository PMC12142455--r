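test_that("planar series have the stated slope, gradient and determinism", {
  g <- grid_spec(5, 6, 10)
  s <- make_planar_series(g, 2001:2010, temporal_trend = 0.05,
                          spatial_gradient = 0.01, noise_sd = 0)
  # temporal slope at every cell is exactly the trend
  for (idx in list(c(1, 1), c(3, 4), c(5, 6))) {
    ys <- s$layers[idx[1], idx[2], ]
    expect_equal(unname(coef(lm(ys ~ I(2001:2010)))[2]), 0.05)
  }
  # x-adjacent cells differ by exactly gradient * cell_size
  expect_equal(s$layers[1, 2, 1] - s$layers[1, 1, 1], 0.01 * 10)
  expect_equal(s$layers[2, 1, 1] - s$layers[1, 1, 1], 0)

  s1 <- make_planar_series(g, 2001:2010, noise_sd = 1, seed = 99)
  s2 <- make_planar_series(g, 2001:2010, noise_sd = 1, seed = 99)
  expect_identical(s1$layers, s2$layers)
  s3 <- make_planar_series(g, 2001:2010, noise_sd = 1, seed = 100)
  expect_false(identical(s1$layers, s3$layers))
})

test_that("future series deliver the requested climatology mean shift", {
  g <- grid_spec(4, 4, 10)
  b <- make_planar_series(g, 1981:2010, noise_sd = 0)
  f <- make_future_series(b, delta_mean = 2, years_future = 2041:2070)
  expect_equal(climatology(f)$mean_grid - climatology(b)$mean_grid,
               matrix(2, 4, 4))

  # delta = 0 with exact SDs: magnitude must vanish everywhere
  f0 <- make_future_series(b, delta_mean = 0, years_future = 2041:2070)
  bt <- climatology(b); bt$variable <- "temperature"
  bp <- climatology(b); bp$variable <- "precipitation"
  ft <- climatology(f0); fp <- climatology(f0)
  sed <- magnitude_sed(list(temperature = bt, precipitation = bp),
                       list(temperature = ft, precipitation = fp),
                       sds = list(temperature = matrix(1, 4, 4),
                                  precipitation = matrix(1, 4, 4)))
  expect_equal(sed$value_grid, matrix(0, 4, 4))

  # noisy case: realized mean shift within 3 * sigma/sqrt(n) per cell
  fn <- make_future_series(b, delta_mean = 2, years_future = 2041:2070,
                           noise_sd = 0.5, seed = 5)
  shift <- climatology(fn)$mean_grid - climatology(b)$mean_grid
  expect_true(all(abs(shift - 2) < 3 * 0.5 / sqrt(30)))
})

test_that("protected landscape reproduces its protection model", {
  g <- grid_spec(40, 40, 10)
  # all slopes zero: protection fraction ~ plogis(intercept)
  m0 <- c(intercept = -1, bio_temp = 0, bio_prec = 0, land_cover = 0,
          human_footprint = 0, elevation = 0)
  land <- make_protected_landscape(g, n_polygons = 0, protection_model = m0,
                                   seed = 31)
  p <- plogis(-1)
  se <- sqrt(p * (1 - p) / 1600)
  expect_lt(abs(mean(land$cells$protected) - p), 3 * se)
  expect_equal(unique(land$cells$true_propensity), p)

  # protection fractions respect the treatment thresholds
  tr <- assign_treatment(land$cells$protection_fraction)
  expect_true(all(land$cells$protection_fraction[tr == "treated"] > 0.5))
  expect_true(all(land$cells$protection_fraction[tr == "control"] < 0.05))

  # degenerate case: no polygons, no error
  expect_s3_class(land$pas, "pa_set")
  expect_identical(length(land$pas), 0L)
})

test_that("landscape polygons are non-overlapping and inside the grid", {
  g <- grid_spec(60, 60, 10)
  land <- make_protected_landscape(g, n_polygons = 15,
                                   area_range = c(100, 1500), seed = 8)
  expect_identical(length(land$pas), 15L)
  bbs <- t(vapply(land$pas$geoms, climrisk:::geom_bbox, numeric(4)))
  for (i in 1:14) for (j in (i + 1):15) {
    disjoint <- bbs[i, "xmax"] < bbs[j, "xmin"] || bbs[i, "xmin"] > bbs[j, "xmax"] ||
      bbs[i, "ymax"] < bbs[j, "ymin"] || bbs[i, "ymin"] > bbs[j, "ymax"]
    expect_true(disjoint)
  }
  expect_true(all(bbs[, "xmin"] >= 0 & bbs[, "xmax"] <= 600))
  expect_true(all(land$pas$table$area_km2 >= 100 &
                    land$pas$table$area_km2 <= 1500))
  # impossible packing errors out rather than looping forever
  expect_error(
    make_protected_landscape(grid_spec(3, 3, 1), n_polygons = 50,
                             area_range = c(4, 8), seed = 1),
    "infeasible")
})

test_that("species occurrences honor occupancy probability and min-one-site", {
  sites <- sprintf("PA%02d", 1:50)
  occ <- make_species_occurrences(1000, sites, occupancy_prob = 0.3, seed = 77)
  expect_true(all(rowSums(occ$incidence) >= 1))
  se <- sqrt(0.3 * 0.7 / (1000 * 50))
  expect_lt(abs(mean(occ$incidence) - 0.3), 3 * se + 1e-3)

  occ1 <- make_species_occurrences(5, sites, occupancy_prob = 1, seed = 1)
  expect_true(all(occ1$incidence))

  occ0 <- make_species_occurrences(20, sites, occupancy_prob = 0, seed = 1)
  expect_true(all(rowSums(occ0$incidence) == 1))

  a <- make_species_occurrences(10, sites, 0.2, range_overlap = TRUE, seed = 3)
  b <- make_species_occurrences(10, sites, 0.2, range_overlap = TRUE, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$range_overlap >= 0 & a$range_overlap <= 1))
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_planar_series(grid_spec(4, 4, 1), 2001:2003, noise_sd = 1,
                               seed = 5))
  invisible(make_species_occurrences(3, c("a", "b"), 0.5, seed = 5))
  expect_identical(.Random.seed, before)
})
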