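#' @title Synthetic study-system generators
#' @description
#' Seeded generators producing (i) planar climate series with known spatial
#' gradient, temporal trend and interannual Gaussian noise, (ii) protected
#' landscapes whose protection probability is confounded with cell
#' covariates, and (iii) species-site occurrence tables. Their parameters
#' define analytically known ground truth for every downstream metric: on a
#' noise-free planar climate with trend r (units/yr) and gradient g
#' (units/km), local velocity is r/g and the analog displacement after t
#' years is r*t/g.
#' @name synthetic-data
NULL

# Evaluate code under a temporary RNG state; global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a planar climate series
#'
#' Cell value for center coordinates (x, y) and calendar year t is
#' `base_value + spatial_gradient * coord + temporal_trend * (t - ref_year)
#' + eps`, with `coord` the x (default) or y center coordinate in km and
#' `eps ~ N(0, noise_sd)` independent per cell-year. Deterministic given
#' `seed`.
#'
#' @param grid A [grid_spec()].
#' @param years Calendar years of the layers.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param base_value Value at coordinate origin in the reference year.
#' @param spatial_gradient Units per km along `gradient_axis`.
#' @param temporal_trend Units per year.
#' @param noise_sd Interannual Gaussian noise SD (>= 0).
#' @param gradient_axis `"x"` or `"y"`.
#' @param ref_year Year at which the trend term is zero; defaults to the
#'   first year. Use a common `ref_year` for baseline and future series to
#'   make the two-period trend exactly linear.
#' @param period_label `"baseline"` or `"future"`.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @return A [climate_series()].
#' @examples
#' g <- grid_spec(5, 5, 10)
#' s <- make_planar_series(g, 1981:2010, temporal_trend = 0.05, noise_sd = 0)
#' @export
make_planar_series <- function(grid, years,
                               variable = "temperature",
                               base_value = 10,
                               spatial_gradient = 0.01,
                               temporal_trend = 0.05,
                               noise_sd = 0,
                               gradient_axis = c("x", "y"),
                               ref_year = years[1],
                               period_label = c("baseline", "future"),
                               seed = NULL) {
  gradient_axis <- match.arg(gradient_axis)
  period_label <- match.arg(period_label)
  stopifnot(noise_sd >= 0)
  cc <- cell_centers(grid)
  coord <- if (gradient_axis == "x")
    matrix(cc$x, grid$n_rows, grid$n_cols, byrow = TRUE)
  else
    matrix(cc$y, grid$n_rows, grid$n_cols)
  spatial <- base_value + spatial_gradient * coord
  layers <- with_seed(seed, {
    vapply(years, function(t) {
      lyr <- spatial + temporal_trend * (t - ref_year)
      if (noise_sd > 0)
        lyr <- lyr + matrix(stats::rnorm(length(lyr), 0, noise_sd),
                            grid$n_rows, grid$n_cols)
      lyr
    }, matrix(0, grid$n_rows, grid$n_cols))
  })
  climate_series(layers, years, variable, grid, period_label)
}

#' Derive a future series with a known mean shift
#'
#' Builds a future-period series whose climatology mean equals the baseline
#' climatology mean plus `delta_mean` exactly when `noise_sd = 0` (the
#' within-period trend is centered on the future period's midpoint so it
#' cancels in the mean). This gives magnitude and analog computations a known
#' per-cell shift.
#'
#' @param baseline A baseline [climate_series()].
#' @param delta_mean Additive mean change, in the variable's units.
#' @param years_future Calendar years of the future period.
#' @param trend_future Units/yr trend within the future period (default 0).
#' @param noise_sd Interannual noise SD (default 0).
#' @param seed Integer seed.
#' @return A [climate_series()] with `period_label = "future"`.
#' @export
make_future_series <- function(baseline, delta_mean, years_future,
                               trend_future = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(baseline, "climate_series"))
  base_mean <- climatology(baseline)$mean_grid
  grid <- baseline$grid
  mid <- mean(years_future)
  layers <- with_seed(seed, {
    vapply(years_future, function(t) {
      lyr <- base_mean + delta_mean + trend_future * (t - mid)
      if (noise_sd > 0)
        lyr <- lyr + matrix(stats::rnorm(length(lyr), 0, noise_sd),
                            grid$n_rows, grid$n_cols)
      lyr
    }, matrix(0, grid$n_rows, grid$n_cols))
  })
  climate_series(layers, years_future, baseline$variable, grid, "future")
}

default_protection_model <- function() {
  c(intercept = -1.2, bio_temp = 0.4, bio_prec = 0, land_cover = 0,
    human_footprint = -0.5, elevation = 0.6)
}

default_outcome_model <- function() {
  c(bio_temp = 0.4, bio_prec = 0, land_cover = 0, human_footprint = 0,
    elevation = -0.3)
}

#' Generate a confounded protected landscape
#'
#' Produces the inputs for the protected-vs-control comparison with known
#' ground truth:
#' * five standard-normal cell covariates emulating the covariate classes
#'   used for matching real protected areas (baseline climate x2, land
#'   cover, human footprint, elevation);
#' * a true protection propensity per cell,
#'   `plogis(protection_model %*% covariates)`, and a Bernoulli protected
#'   indicator drawn from it — protection is therefore *confounded* with the
#'   covariates;
#' * a per-cell protected-area overlap fraction consistent with the
#'   indicator (protected cells > 0.5, unprotected < 0.05, plus a share of
#'   marginal cells in between that the treatment rule excludes);
#' * a synthetic outcome metric `outcome_model %*% covariates + N(0,
#'   outcome_sd) + effect_on_outcome * protected`, so `effect_on_outcome =
#'   0` is an exact null with covariate confounding;
#' * `n_polygons` non-overlapping discs/rectangles with areas in
#'   `area_range` for the zonal stages.
#'
#' @param grid A [grid_spec()].
#' @param n_polygons Number of protected-area polygons (0 allowed).
#' @param area_range Length-2 km^2 bounds for polygon areas.
#' @param protection_model Named coefficients (`intercept` plus covariate
#'   names) of the logistic protection model.
#' @param outcome_model Named covariate coefficients of the linear outcome
#'   model.
#' @param effect_on_outcome Additive outcome shift inside protected cells
#'   (0 = null).
#' @param outcome_sd Outcome noise SD.
#' @param marginal_frac Share of cells given a marginal (5-50%) protection
#'   fraction.
#' @param n_regions Number of vertical biogeographic-region bands.
#' @param max_tries Placement retries per polygon before an infeasible-
#'   packing error.
#' @param seed Integer seed.
#' @return A list with `pas` ([pa_set()]), `cells` (data frame: `cell_id`,
#'   `row`, `col`, `region`, covariates, `true_propensity`, `protected`,
#'   `protection_fraction`, `outcome`), `protection_fraction` and `outcome`
#'   grids, and `params` echoing the generator settings.
#' @export
make_protected_landscape <- function(grid,
                                     n_polygons = 30,
                                     area_range = c(20, 500),
                                     protection_model = default_protection_model(),
                                     outcome_model = default_outcome_model(),
                                     effect_on_outcome = 0,
                                     outcome_sd = 1,
                                     marginal_frac = 0.1,
                                     n_regions = 2,
                                     max_tries = 200,
                                     seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"), marginal_frac >= 0, marginal_frac < 1)
  cov_names <- setdiff(names(protection_model), "intercept")
  if (!"intercept" %in% names(protection_model))
    stop("protection_model must include an 'intercept' coefficient")
  n_cells <- grid$n_rows * grid$n_cols
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_cells * length(cov_names)), n_cells,
                dimnames = list(NULL, cov_names))
    eta <- protection_model["intercept"] + drop(X %*% protection_model[cov_names])
    prop <- stats::plogis(eta)
    if (any(prop <= 0 | prop >= 1)) stop("protection probabilities must lie in (0,1)")
    protected <- stats::rbinom(n_cells, 1, prop) == 1

    frac <- numeric(n_cells)
    frac[protected] <- stats::runif(sum(protected), 0.55, 1)
    frac[!protected] <- stats::runif(sum(!protected), 0, 0.045)
    marginal <- stats::runif(n_cells) < marginal_frac
    frac[marginal] <- stats::runif(sum(marginal), 0.06, 0.49)

    oc <- setdiff(names(outcome_model), "intercept")
    outcome <- drop(X[, oc, drop = FALSE] %*% outcome_model[oc]) +
      stats::rnorm(n_cells, 0, outcome_sd) +
      effect_on_outcome * (protected & !marginal)

    # region bands by column (vertical split of the study area)
    col_of <- rep(seq_len(grid$n_cols), each = grid$n_rows)
    row_of <- rep(seq_len(grid$n_rows), times = grid$n_cols)
    region_id <- pmin(n_regions, 1L + ((col_of - 1L) * n_regions) %/% grid$n_cols)
    region <- sprintf("region_%d", region_id)

    pas <- place_random_polygons(grid, n_polygons, area_range, n_regions,
                                 max_tries)

    cells <- data.frame(cell_id = seq_len(n_cells), row = row_of, col = col_of,
                        region = region, stringsAsFactors = FALSE)
    cells <- cbind(cells, as.data.frame(X))
    cells$true_propensity <- prop
    cells$protected <- protected
    cells$protection_fraction <- frac
    cells$outcome <- outcome

    # cell vectors are in column-major (row fastest) order, matching matrix()
    list(pas = pas,
         cells = cells,
         protection_fraction = matrix(frac, grid$n_rows, grid$n_cols),
         outcome = matrix(outcome, grid$n_rows, grid$n_cols),
         true_propensity = matrix(prop, grid$n_rows, grid$n_cols),
         protected = matrix(protected, grid$n_rows, grid$n_cols),
         params = list(protection_model = protection_model,
                       outcome_model = outcome_model,
                       effect_on_outcome = effect_on_outcome,
                       outcome_sd = outcome_sd, marginal_frac = marginal_frac,
                       n_regions = n_regions))
  })
}

# Non-overlapping discs (odd indices) and squares (even) packed by rejection.
place_random_polygons <- function(grid, n_polygons, area_range, n_regions,
                                  max_tries = 200) {
  if (n_polygons == 0L) return(pa_set(list()))
  width <- grid$n_cols * grid$cell_size
  height <- grid$n_rows * grid$cell_size
  x0 <- grid$origin_x; y0 <- grid$origin_y
  geoms <- vector("list", n_polygons)
  bboxes <- matrix(0, n_polygons, 4)
  regions <- character(n_polygons)
  for (i in seq_len(n_polygons)) {
    area <- stats::runif(1, area_range[1], area_range[2])
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (i %% 2L == 1L) {
        r <- sqrt(area / pi)
        cx <- stats::runif(1, x0 + r, x0 + width - r)
        cy <- stats::runif(1, y0 - height + r, y0 - r)
        g <- geom_disc(c(cx, cy), r)
      } else {
        side <- sqrt(area)
        cx <- stats::runif(1, x0 + side / 2, x0 + width - side / 2)
        cy <- stats::runif(1, y0 - height + side / 2, y0 - side / 2)
        g <- geom_rect(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
      }
      bb <- geom_bbox(g)
      ok <- TRUE
      if (i > 1L) {
        prev <- bboxes[seq_len(i - 1L), , drop = FALSE]
        ok <- all(bb["xmax"] < prev[, 1] | bb["xmin"] > prev[, 3] |
                    bb["ymax"] < prev[, 2] | bb["ymin"] > prev[, 4])
      }
      if (ok) {
        geoms[[i]] <- g
        bboxes[i, ] <- bb
        rid <- pmin(n_regions, 1L + floor(((cx - x0) / width) * n_regions))
        regions[i] <- sprintf("region_%d", rid)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("infeasible polygon packing: could not place polygon %d after %d tries",
                   i, max_tries))
  }
  pa_set(geoms, region = regions)
}

#' Generate a species-site occurrence table
#'
#' Independent Bernoulli(`occupancy_prob`) incidence per species-site pair;
#' species drawing zero sites are redrawn until they occupy at least one
#' (with `occupancy_prob = 0` each species is instead assigned one uniformly
#' chosen site, the minimal occupancy satisfying the invariant).
#'
#' @param n_species Number of species.
#' @param site_ids Site (protected-area polygon) identifiers.
#' @param occupancy_prob Per-site occupancy probability in `[0, 1]`.
#' @param range_overlap If `TRUE`, attach a uniform(0,1) range-overlap
#'   fraction per species (the share of the species range inside the
#'   network, enabling area-weighted exposure).
#' @param seed Integer seed.
#' @return An `occurrence_table`: list with logical `incidence` matrix
#'   (species x sites), `species_id`, `site_ids`, optional `range_overlap`.
#' @export
make_species_occurrences <- function(n_species, site_ids, occupancy_prob = 0.3,
                                     range_overlap = FALSE, seed = NULL) {
  stopifnot(occupancy_prob >= 0, occupancy_prob <= 1, length(site_ids) >= 1)
  n_sites <- length(site_ids)
  with_seed(seed, {
    inc <- matrix(stats::runif(n_species * n_sites) < occupancy_prob,
                  n_species, n_sites)
    empty <- which(rowSums(inc) == 0L)
    if (occupancy_prob == 0) {
      for (i in seq_len(n_species))
        inc[i, sample.int(n_sites, 1L)] <- TRUE
    } else {
      while (length(empty)) {
        inc[empty, ] <- matrix(stats::runif(length(empty) * n_sites) < occupancy_prob,
                               length(empty), n_sites)
        empty <- empty[rowSums(inc[empty, , drop = FALSE]) == 0L]
      }
    }
    overlap <- if (isTRUE(range_overlap)) stats::runif(n_species) else NULL
    structure(list(incidence = inc,
                   species_id = sprintf("sp%04d", seq_len(n_species)),
                   site_ids = as.character(site_ids),
                   range_overlap = overlap),
              class = "occurrence_table")
  })
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("<occurrence_table> %d species x %d sites, mean occupancy %.3f%s\n",
              nrow(x$incidence), ncol(x$incidence), mean(x$incidence),
              if (is.null(x$range_overlap)) "" else ", with range overlap"))
  invisible(x)
}
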