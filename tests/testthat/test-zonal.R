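test_that("zonal median takes the median over covered cell centers", {
  g <- grid_spec(4, 4, 1)  # centers at 0.5, 1.5, 2.5, 3.5
  vals <- matrix(0, 4, 4)
  # craft a rectangle covering exactly three cells with values {1, 2, 9}
  vals[1, 1] <- 1; vals[1, 2] <- 2; vals[1, 3] <- 9
  pas <- pa_set(list(climrisk:::geom_rect(0, -1, 3, 0)), "r1")
  expect_equal(unname(zonal_median(vals, pas, grid = g)), 2)

  # constant field: median is the constant for every polygon
  pas2 <- pa_set(list(climrisk:::geom_rect(0, -3, 2, 0),
                      climrisk:::geom_disc(c(2.5, -2.5), 1.2)), c("a", "b"))
  expect_equal(unname(zonal_median(matrix(7, 4, 4), pas2, grid = g)), c(7, 7))

  expect_error(zonal_median(vals, pa_set(list()), grid = g), "empty polygon")
  tiny <- pa_set(list(climrisk:::geom_rect(0.6, -0.9, 0.9, -0.6)), "t")
  expect_warning(zonal_median(vals, tiny, grid = g), "no valid cell center")
})

test_that("zonal median equals a cell-enumeration oracle and polygon splits", {
  g <- grid_spec(10, 10, 5)
  set.seed(17)
  vals <- matrix(rnorm(100), 10, 10)
  rect <- climrisk:::geom_rect(7, -41, 33, -9)
  pas <- pa_set(list(rect), "R")
  got <- unname(zonal_median(vals, pas, grid = g))
  cc <- cell_centers(g)
  inside <- outer(cc$y, cc$x, function(y, x) x > 7 & x < 33 & y > -41 & y < -9)
  expect_equal(got, median(vals[inside]))

  # splitting the rectangle into two parts covering the same cells changes
  # nothing when the median is recomputed over the union of their cells
  left <- climrisk:::geom_rect(7, -41, 20.5, -9)   # split between centers
  right <- climrisk:::geom_rect(20.5, -41, 33, -9)
  pas2 <- pa_set(list(left, right), c("L", "R"))
  cells_union <- rbind(cells_in_geom(g, left), cells_in_geom(g, right))
  expect_equal(median(vals[cells_union]), got)

  # vertex order does not matter
  poly_rev <- climrisk:::geom_polygon(climrisk:::geom_rect(7, -41, 33, -9)$coords[4:1, ])
  expect_equal(unname(zonal_median(vals, pa_set(list(poly_rev), "rev"),
                                   grid = g)), got)
})

test_that("residence time follows d/gV with floor handling and scaling", {
  expect_equal(as.numeric(residence_time(pi, 1)), 2)
  expect_equal(as.numeric(residence_time(100 * pi, 5)), 4)
  expect_error(residence_time(-1, 1), "positive")
  expect_error(residence_time(1, -0.1), "non-negative")

  rt <- residence_time(pi, 0.001, velocity_floor = 0.01)
  expect_equal(as.numeric(rt), 2 / 0.01)
  expect_true(attr(rt, "floored"))

  # sqrt(area) scaling at fixed velocity; 1/velocity at fixed area
  expect_equal(as.numeric(residence_time(400, 2)) /
                 as.numeric(residence_time(100, 2)), 2)
  expect_equal(as.numeric(residence_time(100, 4)) /
                 as.numeric(residence_time(100, 2)), 0.5)
})

test_that("disc residence time recovers through the full zonal pipeline", {
  # uniform local velocity 2 km/yr (trend 0.02, gradient 0.01) and a disc of
  # radius 10 km: residence time = 2*10/2 = 10 yr
  g <- grid_spec(30, 30, 2)
  ps <- planar_setup(g, trend = 0.02, gradient = 0.01)
  tr <- temporal_trend(ps$baseline, ps$future)
  gr <- spatial_gradient(climatology(ps$baseline))
  vel <- local_velocity(tr, gr)
  pas <- pa_set(list(climrisk:::geom_disc(c(30, -30), 10)), "disc",
                region = "r1")
  tab <- pa_exposure_table(pas, list(local_velocity = vel))
  expect_equal(tab$area_km2, 100 * pi)
  expect_equal(tab$diameter_km, 20)
  expect_equal(tab$residence_time_yr, 10, tolerance = 0.02)
})

test_that("species exposure aggregates site medians and area weights", {
  occ <- list(incidence = matrix(c(TRUE, FALSE, TRUE,    # s1: sites A, C
                                   FALSE, TRUE, TRUE),   # s2: sites B, C
                                 2, 3, byrow = TRUE),
              species_id = c("s1", "s2"), site_ids = c("A", "B", "C"),
              range_overlap = NULL)
  class(occ) <- "occurrence_table"
  sv <- data.frame(site_id = c("A", "B", "C"), metric = c(1, 5, 3))
  out <- species_exposure(occ, sv)
  expect_equal(out$median_metric, c(median(c(1, 3)), median(c(5, 3))))

  # equal-area sites with values {1, 3}: median 2 and weighted 2
  occ1 <- occ; occ1$incidence <- matrix(c(TRUE, TRUE, FALSE), 1, 3)
  occ1$species_id <- "s1"
  sv2 <- data.frame(site_id = c("A", "B", "C"), metric = c(1, 3, 99))
  out2 <- species_exposure(occ1, sv2,
                           site_areas = c(A = 50, B = 50, C = 10))
  expect_equal(out2$median_metric, 2)
  expect_equal(out2$weighted_metric, 2)

  # one-site species: species value equals the site value
  occ2 <- occ1; occ2$incidence <- matrix(c(FALSE, FALSE, TRUE), 1, 3)
  expect_equal(species_exposure(occ2, sv2)$median_metric, 99)

  expect_error(species_exposure(occ, sv[1:2, ]), "missing from site_values")
})

test_that("species exposure equals a per-species enumeration oracle", {
  set.seed(23)
  occ <- make_species_occurrences(40, sprintf("P%02d", 1:12), 0.4, seed = 6)
  sv <- data.frame(site_id = occ$site_ids, m1 = rnorm(12), m2 = runif(12))
  areas <- setNames(runif(12, 10, 100), occ$site_ids)
  out <- species_exposure(occ, sv, site_areas = areas)
  for (i in c(1, 17, 40)) {
    sel <- occ$incidence[i, ]
    expect_equal(out$median_m1[i], median(sv$m1[sel]))
    expect_equal(out$median_m2[i], median(sv$m2[sel]))
    expect_equal(out$weighted_m1[i],
                 sum(sv$m1[sel] * areas[sel]) / sum(areas[sel]))
  }
})

test_that("protection fractions and GeoJSON round-trips are faithful", {
  g <- grid_spec(10, 10, 10)
  # a rectangle aligned with whole cells: fractions exactly 0 or 1
  pas <- pa_set(list(climrisk:::geom_rect(20, -60, 50, -20)), "R1", "reg")
  frac <- protection_fraction(g, pas, subsamples = 4)
  expect_true(all(frac %in% c(0, 1)))
  expect_equal(sum(frac), 3 * 4)  # 30 x 40 km of 10 km cells

  pas2 <- pa_set(list(climrisk:::geom_disc(c(50, -50), 23),
                      climrisk:::geom_rect(5, -95, 35, -75)),
                 c("d", "r"), c("alpha", "beta"))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_pa_geojson(pas2, path)
  back <- read_pa_geojson(path)
  expect_equal(back$table$area_km2, pas2$table$area_km2, tolerance = 1e-9)
  expect_equal(back$table$region, pas2$table$region)
  expect_equal(back$geoms[[1]]$radius, 23)
  expect_equal(back$geoms[[2]]$coords, pas2$geoms[[2]]$coords,
               ignore_attr = TRUE)
})
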