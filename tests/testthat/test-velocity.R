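test_that("temporal trend matches closed forms and a least-squares oracle", {
  g <- grid_spec(4, 4, 10)
  ps <- planar_setup(g, trend = 0.05, gradient = 0.01)
  tr <- temporal_trend(ps$baseline, ps$future)
  expect_equal(tr$slope_grid, matrix(0.05, 4, 4), tolerance = 1e-12)

  # two flat blocks 10 -> 13 with midpoints 60 yr apart: slope 3/60
  b <- climate_series(array(10, c(4, 4, 30)), 1981:2010, "temperature", g)
  f <- climate_series(array(13, c(4, 4, 30)), 2041:2070, "temperature", g,
                      period_label = "future")
  tr2 <- temporal_trend(b, f)
  lm_oracle <- unname(coef(lm(y ~ x, data.frame(
    x = c(1981:2010, 2041:2070), y = rep(c(10, 13), each = 30))))[2])
  expect_equal(tr2$slope_grid[2, 2], lm_oracle, tolerance = 1e-12)
  # closed form for the two-block design: the within-block year variance
  # enters the denominator, so the slope is below the midpoint ratio 3/60
  expect_equal(tr2$slope_grid[1, 1], 2700 / 58495, tolerance = 1e-12)

  # per-period mode averages the two within-period slopes (0 here)
  tr3 <- temporal_trend(b, f, mode = "per_period")
  expect_equal(tr3$slope_grid, matrix(0, 4, 4))

  expect_error(temporal_trend(b, climate_series(array(1, c(4, 4, 1)), 2041,
                                                "temperature", g, "future")),
               "at least 2 years")
})

test_that("noisy trend estimates sit within OLS sampling bounds", {
  g <- grid_spec(20, 20, 10)
  ps <- planar_setup(g, trend = 0.05, noise_sd = 0.5, seed = 21)
  tr <- temporal_trend(ps$baseline, ps$future)
  z <- abs(tr$slope_grid - 0.05) / tr$stderr_grid
  # >= 99% of cells within 3 SE of the generating trend
  expect_gte(mean(z < 3), 0.99)
})

test_that("spatial gradient matches planar fields and a brute-force oracle", {
  g <- grid_spec(6, 6, 10)
  b <- make_planar_series(g, 2001:2005, spatial_gradient = 0.01, noise_sd = 0)
  gr <- spatial_gradient(climatology(b))
  expect_equal(gr$magnitude_grid, matrix(0.01, 6, 6), tolerance = 1e-12)

  const <- climate_series(array(3, c(6, 6, 3)), 2001:2003, "temperature", g)
  expect_equal(spatial_gradient(climatology(const))$magnitude_grid,
               matrix(0, 6, 6))

  # random 5x5 grid, including a nodata hole, vs the exhaustive oracle
  g5 <- grid_spec(5, 5, 7)
  set.seed(13)
  M <- matrix(rnorm(25), 5, 5)
  M[2, 4] <- NA
  cl <- structure(list(mean_grid = M, sd_grid = abs(M), grid = g5,
                       variable = "temperature", period_label = "baseline",
                       years = 1:2), class = "climatology")
  gr5 <- spatial_gradient(cl)
  expect_equal(gr5$magnitude_grid, oracle_gradient(M, 7), tolerance = 1e-12)
})

test_that("local velocity divides trend by gradient with a floor", {
  g <- grid_spec(4, 4, 10)
  mk_trend <- function(v) structure(list(
    slope_grid = matrix(v, 4, 4), stderr_grid = matrix(0, 4, 4),
    variable = "temperature", grid = g), class = "trend_field")
  mk_grad <- function(v) structure(list(
    magnitude_grid = matrix(v, 4, 4), ew_grid = matrix(v, 4, 4),
    ns_grid = matrix(0, 4, 4), angle_grid = matrix(0, 4, 4),
    variable = "temperature", grid = g), class = "gradient_field")

  expect_equal(local_velocity(mk_trend(0.05), mk_grad(0.01))$value_grid,
               matrix(5, 4, 4))
  expect_equal(local_velocity(mk_trend(0), mk_grad(0.01))$value_grid,
               matrix(0, 4, 4))
  # gradient below the floor: capped at slope/floor and flagged
  v <- local_velocity(mk_trend(0.05), mk_grad(1e-6), gradient_floor = 1e-4)
  expect_equal(v$value_grid, matrix(0.05 / 1e-4, 4, 4))
  expect_true(all(v$flags))
  v2 <- local_velocity(mk_trend(0.05), mk_grad(0.01), gradient_floor = 1e-4)
  expect_false(any(v2$flags))
  expect_error(local_velocity(mk_trend(1), mk_grad(1), gradient_floor = 0),
               "positive")
  # sign retained: a declining variable gives negative velocity
  expect_lt(local_velocity(mk_trend(-0.02), mk_grad(0.01))$value_grid[1, 1], 0)
})

test_that("absolute-sum combination is elementwise and order-invariant", {
  g <- grid_spec(4, 5, 10)
  set.seed(3)
  a <- matrix(rnorm(20), 4, 5); b <- matrix(rnorm(20), 4, 5)
  fa <- exposure_field(a, "local_velocity", g)
  fb <- exposure_field(b, "local_velocity", g)
  expect_equal(combine_abs_sum(fa, fb)$value_grid, abs(a) + abs(b))
  expect_equal(combine_abs_sum(fa, fb)$value_grid,
               combine_abs_sum(fb, fa)$value_grid)
  expect_equal(combine_abs_sum(
    exposure_field(matrix(3, 4, 5), "local_velocity", g),
    exposure_field(matrix(-1, 4, 5), "local_velocity", g))$value_grid[1, 1], 4)
  fm <- exposure_field(a, "magnitude", g)
  expect_error(combine_abs_sum(fa, fm), "metric mismatch")
})

test_that("magnitude SED matches its formula, scale invariance and oracle", {
  g <- grid_spec(4, 4, 10)
  mk_clim <- function(mean_v, sd_v, var) structure(list(
    mean_grid = matrix(mean_v, 4, 4), sd_grid = matrix(sd_v, 4, 4),
    variable = var, period_label = "baseline", grid = g, years = 1:2),
    class = "climatology")
  base <- list(temperature = mk_clim(0, 1, "temperature"),
               precipitation = mk_clim(0, 1, "precipitation"))
  fut <- list(temperature = mk_clim(3, 1, "temperature"),
              precipitation = mk_clim(4, 1, "precipitation"))
  expect_equal(magnitude_sed(base, fut)$value_grid, matrix(5, 4, 4))

  fut2 <- list(temperature = mk_clim(2, 1, "temperature"),
               precipitation = mk_clim(0, 1, "precipitation"))
  expect_equal(magnitude_sed(base, fut2)$value_grid, matrix(2, 4, 4))

  # joint rescaling of (b - a) and s leaves the SED unchanged
  set.seed(4)
  A <- matrix(rnorm(16), 4, 4); B <- matrix(rnorm(16), 4, 4)
  S <- matrix(runif(16, 0.5, 2), 4, 4)
  clA <- function(M, v) { c <- mk_clim(0, 1, v); c$mean_grid <- M; c }
  sed1 <- magnitude_sed(list(temperature = clA(A, "t"), precipitation = clA(A, "p")),
                        list(temperature = clA(B, "t"), precipitation = clA(B, "p")),
                        sds = list(temperature = S, precipitation = S))
  k <- 3.7
  sed2 <- magnitude_sed(list(temperature = clA(k * A, "t"), precipitation = clA(k * A, "p")),
                        list(temperature = clA(k * B, "t"), precipitation = clA(k * B, "p")),
                        sds = list(temperature = k * S, precipitation = k * S))
  expect_equal(sed1$value_grid, sed2$value_grid, tolerance = 1e-12)
  # elementwise oracle
  oracle <- sqrt(2 * (B - A)^2 / S^2)
  expect_equal(sed1$value_grid, oracle, tolerance = 1e-12)

  # zero SD -> nodata
  S0 <- S; S0[2, 2] <- 0
  sed0 <- magnitude_sed(list(temperature = clA(A, "t"), precipitation = clA(A, "p")),
                        list(temperature = clA(B, "t"), precipitation = clA(B, "p")),
                        sds = list(temperature = S0, precipitation = S))
  expect_true(is.na(sed0$value_grid[2, 2]))
  expect_error(magnitude_sed(base["temperature"], fut["temperature"]),
               "variable set mismatch")
})

test_that("ensembles summarize members with sample SD and strict validity", {
  g <- grid_spec(4, 4, 10)
  mk <- function(v, esm = "e") exposure_field(matrix(v, 4, 4), "magnitude", g,
                                              esm = esm)
  ens <- ensemble_fields(list(mk(1, "a"), mk(2, "b"), mk(3, "c")))
  expect_equal(ens$mean_grid, matrix(2, 4, 4))
  expect_equal(ens$sd_grid, matrix(1, 4, 4))
  expect_equal(ens$member_labels, c("a", "b", "c"))

  same <- ensemble_fields(list(mk(7), mk(7)))
  expect_equal(same$sd_grid, matrix(0, 4, 4))

  set.seed(5)
  ms <- lapply(1:4, function(i) mk(0))
  for (i in 1:4) ms[[i]]$value_grid <- matrix(rnorm(16), 4, 4)
  A <- sapply(ms, function(m) as.vector(m$value_grid))
  enr <- ensemble_fields(ms)
  expect_equal(as.vector(enr$mean_grid), rowMeans(A), tolerance = 1e-12)
  expect_equal(as.vector(enr$sd_grid), apply(A, 1, sd), tolerance = 1e-12)

  # partial validity: cell NA in one member is NA with n_valid recorded
  ms[[2]]$value_grid[3, 3] <- NA
  enp <- ensemble_fields(ms)
  expect_true(is.na(enp$mean_grid[3, 3]))
  expect_equal(enp$n_valid_grid[3, 3], 3)
  expect_error(ensemble_fields(list(mk(1),
                                    exposure_field(matrix(1, 4, 4),
                                                   "local_velocity", g))),
               "mixed metrics")
  expect_error(ensemble_fields(list(mk(1))), "at least 2")
})
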