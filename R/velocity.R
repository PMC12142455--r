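#' @title Gradient-based climate velocity and climate-change magnitude
#' @description
#' Local climate velocity is the ratio of a variable's temporal trend
#' (units/yr, an OLS slope on yearly values) to its local spatial gradient
#' (units/km, from a 3x3 neighborhood), giving the speed in km/yr at which
#' an isopleth of that variable moves across the landscape. Climate-change
#' magnitude is the standardized Euclidean distance (SED) between baseline
#' and future climatologies, scaling each variable's change by its baseline
#' interannual SD.
#' @name velocity-metrics
NULL

#' Per-cell temporal trend across the two study periods
#'
#' Fits, per cell, an ordinary least-squares slope of the yearly values on
#' calendar year over the concatenated baseline + future series (the gap
#' between the periods is simply absent from the predictor). An alternative
#' `"per_period"` mode averages the two within-period slopes instead.
#'
#' @param baseline,future [climate_series()] objects sharing grid and
#'   variable, each with at least 2 years.
#' @param mode `"concatenated"` (default) or `"per_period"`.
#' @return A `trend_field`: list with `slope_grid` (units/yr),
#'   `stderr_grid` (OLS standard error of the slope; `NA` in
#'   `"per_period"` mode), `variable`, `grid`.
#' @examples
#' g <- grid_spec(4, 4, 10)
#' b <- make_planar_series(g, 1981:2010, temporal_trend = 0.05, noise_sd = 0)
#' f <- make_planar_series(g, 2041:2070, temporal_trend = 0.05, noise_sd = 0,
#'                         ref_year = 1981, period_label = "future")
#' temporal_trend(b, f)$slope_grid[1, 1]  # 0.05
#' @export
temporal_trend <- function(baseline, future, mode = c("concatenated", "per_period")) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "climate_series"), inherits(future, "climate_series"))
  stop_if_grid_mismatch(baseline$grid, future$grid, "baseline and future series")
  if (baseline$variable != future$variable)
    stop("baseline and future series must be the same variable")
  if (n_years(baseline) < 2L || n_years(future) < 2L)
    stop("each period needs at least 2 years to fit a trend")
  if (mode == "per_period") {
    s1 <- ols_slope(baseline$layers, baseline$years)
    s2 <- ols_slope(future$layers, future$years)
    return(structure(list(slope_grid = (s1$slope + s2$slope) / 2,
                          stderr_grid = matrix(NA_real_, baseline$grid$n_rows,
                                               baseline$grid$n_cols),
                          variable = baseline$variable, grid = baseline$grid),
                     class = "trend_field"))
  }
  years <- c(baseline$years, future$years)
  L <- array(c(baseline$layers, future$layers),
             c(dim(baseline$layers)[1:2], length(years)))
  fit <- ols_slope(L, years)
  structure(list(slope_grid = fit$slope, stderr_grid = fit$stderr,
                 variable = baseline$variable, grid = baseline$grid),
            class = "trend_field")
}

# Vectorized per-cell OLS of layer values on x; any-NA cells -> NA.
ols_slope <- function(L, x) {
  x <- as.numeric(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate predictor: all years equal")
  n <- length(x)
  any_na <- apply(is.na(L), c(1, 2), any)
  dims <- dim(L)
  M <- matrix(L, dims[1] * dims[2], dims[3])
  slope <- drop(M %*% xc) / sxx
  intercept_part <- rowMeans(M)
  fitted <- outer(intercept_part, rep(1, n)) + outer(slope, xc)
  rss <- rowSums((M - fitted)^2)
  stderr <- if (n > 2) sqrt(rss / (n - 2) / sxx) else rep(NA_real_, length(slope))
  slope <- matrix(slope, dims[1], dims[2])
  stderr <- matrix(stderr, dims[1], dims[2])
  slope[any_na] <- NA_real_
  stderr[any_na] <- NA_real_
  list(slope = slope, stderr = stderr)
}

#' @export
print.trend_field <- function(x, ...) {
  cat(sprintf("<trend_field> %s, grid %s, median slope %.4g /yr\n",
              x$variable, format(x$grid),
              stats::median(x$slope_grid, na.rm = TRUE)))
  invisible(x)
}

#' Local spatial gradient from a 3x3 neighborhood
#'
#' For each focal cell the west-east component is the mean of the adjacent
#' column-pair differences inside the 3x3 neighborhood (up to 6), divided by
#' the cell size; the north-south component is the analogous row-pair mean.
#' The gradient magnitude is the vector sum of the two components. Border
#' cells use whatever neighbors exist; nodata neighbors are excluded, and a
#' cell whose neighborhood holds no valid pair on either axis is nodata.
#'
#' @param clim A [climatology()] (the mean grid is differentiated).
#' @return A `gradient_field`: list with `magnitude_grid` (units/km, >= 0),
#'   `ew_grid`, `ns_grid` (signed components, positive east/north),
#'   `angle_grid` (radians, atan2(NS, EW)), `variable`, `grid`.
#' @export
spatial_gradient <- function(clim) {
  stopifnot(inherits(clim, "climatology"))
  M <- clim$mean_grid
  g <- clim$grid
  nr <- nrow(M); nc <- ncol(M)
  # adjacent-pair differences: D_ew[i, j] = (M[i, j+1] - M[i, j]) / cell
  D_ew <- (M[, -1, drop = FALSE] - M[, -nc, drop = FALSE]) / g$cell_size
  # D_ns[i, j] = (M[i, j] - M[i+1, j]) / cell  (positive = increasing north)
  D_ns <- (M[-nr, , drop = FALSE] - M[-1, , drop = FALSE]) / g$cell_size
  # focal (i, j) averages D_ew over rows i-1..i+1 and pair columns j-1, j;
  # expressed as shifts on the (nr x nc-1) difference array, then aligned.
  ew <- shift_mean_pairs(D_ew, axis = "col", nr, nc)
  ns <- shift_mean_pairs(D_ns, axis = "row", nr, nc)
  mag <- sqrt(ew^2 + ns^2)
  structure(list(magnitude_grid = mag, ew_grid = ew, ns_grid = ns,
                 angle_grid = atan2(ns, ew), variable = clim$variable,
                 grid = g),
            class = "gradient_field")
}

# Average the difference array D over the 3x2 (or 2x3) window centred on
# each focal cell: rows i-1..i+1 x pairs {j-1, j} for axis = "col".
shift_mean_pairs <- function(D, axis, nr, nc) {
  out_sum <- matrix(0, nr, nc)
  out_cnt <- matrix(0L, nr, nc)
  if (axis == "col") {
    np <- nc - 1L
    for (dr in -1:1) for (pj in c(-1L, 0L)) {
      # pair index p = j + pj must lie in 1..np; source row i + dr in 1..nr
      rows <- seq_len(nr); cols <- seq_len(nc)
      src_r <- rows + dr
      ok_r <- src_r >= 1L & src_r <= nr
      src_p <- cols + pj
      ok_p <- src_p >= 1L & src_p <= np
      if (!any(ok_r) || !any(ok_p)) next
      v <- D[src_r[ok_r], src_p[ok_p], drop = FALSE]
      valid <- !is.na(v)
      bs <- out_sum[rows[ok_r], cols[ok_p], drop = FALSE]
      bc <- out_cnt[rows[ok_r], cols[ok_p], drop = FALSE]
      bs[valid] <- bs[valid] + v[valid]
      bc[valid] <- bc[valid] + 1L
      out_sum[rows[ok_r], cols[ok_p]] <- bs
      out_cnt[rows[ok_r], cols[ok_p]] <- bc
    }
  } else {
    np <- nr - 1L
    for (dc in -1:1) for (pr in c(-1L, 0L)) {
      rows <- seq_len(nr); cols <- seq_len(nc)
      src_p <- rows + pr
      ok_p <- src_p >= 1L & src_p <= np
      src_c <- cols + dc
      ok_c <- src_c >= 1L & src_c <= nc
      if (!any(ok_p) || !any(ok_c)) next
      v <- D[src_p[ok_p], src_c[ok_c], drop = FALSE]
      valid <- !is.na(v)
      bs <- out_sum[rows[ok_p], cols[ok_c], drop = FALSE]
      bc <- out_cnt[rows[ok_p], cols[ok_c], drop = FALSE]
      bs[valid] <- bs[valid] + v[valid]
      bc[valid] <- bc[valid] + 1L
      out_sum[rows[ok_p], cols[ok_c]] <- bs
      out_cnt[rows[ok_p], cols[ok_c]] <- bc
    }
  }
  out <- out_sum / out_cnt
  out[out_cnt == 0L] <- NA_real_
  out
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %s, grid %s, median magnitude %.4g /km\n",
              x$variable, format(x$grid),
              stats::median(x$magnitude_grid, na.rm = TRUE)))
  invisible(x)
}

#' Local (gradient-based) climate velocity
#'
#' Velocity = temporal trend / spatial gradient, in km/yr. The ratio is
#' singular where the landscape is climatically flat, so gradients below
#' `gradient_floor` are replaced by the floor and the affected cells flagged;
#' the sign of the trend is retained (negative = variable declining), and
#' absolute values are only taken when combining variables with
#' [combine_abs_sum()].
#'
#' @param trend A `trend_field` from [temporal_trend()].
#' @param grad A `gradient_field` from [spatial_gradient()].
#' @param gradient_floor Minimum gradient (units/km), > 0. Default 1e-4.
#' @param scenario,esm Provenance labels.
#' @return An [exposure_field()] with `metric = "local_velocity"` and a
#'   `flags` matrix marking floored cells.
#' @examples
#' # trend 0.05 degC/yr over gradient 0.01 degC/km -> 5 km/yr
#' @export
local_velocity <- function(trend, grad, gradient_floor = 1e-4,
                           scenario = "unspecified", esm = "unspecified") {
  stopifnot(inherits(trend, "trend_field"), inherits(grad, "gradient_field"))
  stop_if_grid_mismatch(trend$grid, grad$grid, "trend and gradient fields")
  if (!is.numeric(gradient_floor) || length(gradient_floor) != 1L ||
      gradient_floor <= 0)
    stop("gradient_floor must be a single positive number")
  gmag <- grad$magnitude_grid
  floored <- !is.na(gmag) & gmag < gradient_floor
  denom <- pmax(gmag, gradient_floor)
  v <- trend$slope_grid / denom
  exposure_field(v, "local_velocity", trend$grid, flags = floored,
                 scenario = scenario, esm = esm)
}

#' Absolute sum of two per-variable velocity fields
#'
#' Combines the per-variable signed local velocities into a single exposure
#' surface as |v_temperature| + |v_precipitation|.
#'
#' @param v_temp,v_prec [exposure_field()]s with the same metric and grid.
#' @return An [exposure_field()] with the shared metric.
#' @export
combine_abs_sum <- function(v_temp, v_prec) {
  stopifnot(inherits(v_temp, "exposure_field"), inherits(v_prec, "exposure_field"))
  if (v_temp$metric != v_prec$metric)
    stop(sprintf("metric mismatch: %s vs %s", v_temp$metric, v_prec$metric))
  stop_if_grid_mismatch(v_temp$grid, v_prec$grid, "velocity fields")
  exposure_field(abs(v_temp$value_grid) + abs(v_prec$value_grid),
                 v_temp$metric, v_temp$grid,
                 scenario = v_temp$scenario, esm = v_temp$esm)
}

#' Climate-change magnitude (standardized Euclidean distance)
#'
#' `SED_i = sqrt( sum_k (b_ki - a_ki)^2 / s_ki^2 )` with `a`/`b` the
#' baseline/future climatology means of variable `k` at cell `i` and `s` the
#' baseline interannual SD. Cells where any `s_ki = 0` (or is nodata) are
#' nodata: a zero-variability cell has no scale on which to standardize.
#'
#' @param base_clims,future_clims Named lists of [climatology()] objects, one
#'   per variable; names must match the configured `variables` set.
#' @param sds Optional named list of SD grids overriding the baseline
#'   climatologies' `sd_grid` (useful for analytically controlled tests).
#' @param variables Required variable set (default temperature +
#'   precipitation).
#' @param scenario,esm Provenance labels.
#' @return An [exposure_field()] with `metric = "magnitude"`
#'   (dimensionless, >= 0).
#' @examples
#' # per-variable shifts (3, 4) with unit SDs -> SED 5
#' @export
magnitude_sed <- function(base_clims, future_clims, sds = NULL,
                          variables = c("temperature", "precipitation"),
                          scenario = "unspecified", esm = "unspecified") {
  check_variable_set(base_clims, future_clims, variables)
  grid <- base_clims[[1]]$grid
  total <- matrix(0, grid$n_rows, grid$n_cols)
  for (v in variables) {
    a <- base_clims[[v]]$mean_grid
    b <- future_clims[[v]]$mean_grid
    s <- if (is.null(sds)) base_clims[[v]]$sd_grid else sds[[v]]
    s[!is.na(s) & s == 0] <- NA_real_
    total <- total + (b - a)^2 / s^2
  }
  exposure_field(sqrt(total), "magnitude", grid,
                 scenario = scenario, esm = esm)
}

check_variable_set <- function(base_clims, future_clims, variables) {
  if (!setequal(names(base_clims), variables) ||
      !setequal(names(future_clims), variables))
    stop(sprintf("variable set mismatch: need exactly {%s}",
                 paste(variables, collapse = ", ")))
  grid <- base_clims[[1]]$grid
  for (v in variables) {
    stopifnot(inherits(base_clims[[v]], "climatology"),
              inherits(future_clims[[v]], "climatology"))
    stop_if_grid_mismatch(grid, base_clims[[v]]$grid, "baseline climatologies")
    stop_if_grid_mismatch(grid, future_clims[[v]]$grid, "future climatologies")
  }
  invisible(TRUE)
}

#' Multi-model ensemble summary of an exposure metric
#'
#' Per-cell mean and sample SD over Earth-System-Model members of one metric
#' under one scenario. A cell is valid only where all members are valid;
#' cells valid in some but not all members (e.g. no-analog in one ESM) are
#' reported through the `n_valid_grid` layer.
#'
#' @param members List of >= 2 [exposure_field()]s with identical metric,
#'   scenario and grid.
#' @return An `ensemble_field`: list with `mean_grid`, `sd_grid`,
#'   `n_valid_grid`, `member_labels`, `metric`, `scenario`, `grid`.
#' @export
ensemble_fields <- function(members) {
  if (length(members) < 2L) stop("ensemble needs at least 2 members")
  metric <- members[[1]]$metric
  scenario <- members[[1]]$scenario
  grid <- members[[1]]$grid
  for (m in members) {
    stopifnot(inherits(m, "exposure_field"))
    if (m$metric != metric)
      stop(sprintf("mixed metrics in ensemble: %s vs %s", metric, m$metric))
    stop_if_grid_mismatch(grid, m$grid, "ensemble members")
  }
  A <- array(unlist(lapply(members, `[[`, "value_grid")),
             c(grid$n_rows, grid$n_cols, length(members)))
  n_valid <- rowSums(!is.na(A), dims = 2)
  all_valid <- n_valid == length(members)
  mean_g <- rowMeans(A, dims = 2)
  sd_g <- sqrt(rowSums((A - array(mean_g, dim(A)))^2, dims = 2) /
                 (length(members) - 1))
  mean_g[!all_valid] <- NA_real_
  sd_g[!all_valid] <- NA_real_
  structure(list(mean_grid = mean_g, sd_grid = sd_g,
                 n_valid_grid = n_valid,
                 member_labels = vapply(members, `[[`, "", "esm"),
                 metric = metric, scenario = scenario, grid = grid),
            class = "ensemble_field")
}

#' @export
print.ensemble_field <- function(x, ...) {
  cat(sprintf("<ensemble_field> %s [%s], %d members (%s), grid %s\n",
              x$metric, x$scenario, length(x$member_labels),
              paste(x$member_labels, collapse = ", "), format(x$grid)))
  cat(sprintf("  ensemble median %.4g, median member SD %.4g\n",
              stats::median(x$mean_grid, na.rm = TRUE),
              stats::median(x$sd_grid, na.rm = TRUE)))
  invisible(x)
}
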