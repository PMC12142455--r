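#' Analog (distance-based) climate velocity
#'
#' For each focal cell `i` the search finds the geographically closest cell
#' `j` whose FUTURE climate is an analog of `i`'s current climate: the
#' standardized difference vector `(b_kj - a_ki) / s_ki` (one component per
#' variable, scaled by the focal cell's baseline interannual SD) must have
#' Euclidean norm at most `threshold_sd`. The metric is the planar
#' center-to-center distance `d` to that analog divided by the elapsed time
#' between the period midpoints; a cell that is its own analog has velocity
#' 0, and a cell with no qualifying analog within `radius_km` is flagged
#' no-analog and left nodata.
#'
#' The search expands over concentric rings with early termination and is
#' exactly equivalent to an exhaustive all-pairs scan (deterministic
#' tie-breaks: nearest distance, then smallest dissimilarity, then row-major
#' cell order). Cells with zero or missing interannual SD cannot be
#' standardized and are returned nodata (a message reports their count).
#'
#' @param base_clims,future_clims Named lists of [climatology()] objects,
#'   one per variable (any number of variables >= 1; the two lists must use
#'   the same names and grids).
#' @param sds Optional named list of SD grids overriding the baseline
#'   climatologies' `sd_grid`.
#' @param threshold_sd Dissimilarity threshold in SD units (default 1.5).
#' @param radius_km Search radius around each focal cell (default 1500 km).
#' @param elapsed_yr Years between the baseline and future climatology
#'   midpoints (default 60, e.g. 1981-2010 vs 2041-2070).
#' @param scenario,esm Provenance labels.
#' @return An [exposure_field()] with `metric = "analog_velocity"` (km/yr,
#'   >= 0), a `no_analog_mask`, and auxiliary grids `distance_grid` (km) and
#'   `analog_index_grid` (1-based row-major index of the analog cell).
#' @examples
#' # a uniform warming over a west-east gradient displaces every isotherm
#' # up-gradient by delta/gradient km; see the package vignette
#' @export
analog_velocity <- function(base_clims, future_clims, sds = NULL,
                            threshold_sd = 1.5, radius_km = 1500,
                            elapsed_yr = 60,
                            scenario = "unspecified", esm = "unspecified") {
  if (!length(base_clims)) stop("need at least one climate variable")
  vars <- names(base_clims)
  if (is.null(vars) || !setequal(vars, names(future_clims)))
    stop("base_clims and future_clims must be named lists over the same variables")
  if (!is.numeric(threshold_sd) || threshold_sd <= 0)
    stop("threshold_sd must be positive")
  if (!is.numeric(radius_km) || radius_km <= 0)
    stop("radius_km must be positive")
  if (!is.numeric(elapsed_yr) || elapsed_yr <= 0)
    stop("elapsed_yr must be positive")
  grid <- base_clims[[1]]$grid
  for (v in vars) {
    stop_if_grid_mismatch(grid, base_clims[[v]]$grid, "baseline climatologies")
    stop_if_grid_mismatch(grid, future_clims[[v]]$grid, "future climatologies")
  }
  a <- lapply(base_clims, `[[`, "mean_grid")
  b <- lapply(future_clims[vars], `[[`, "mean_grid")
  s <- if (is.null(sds)) lapply(base_clims, `[[`, "sd_grid") else sds[vars]
  res <- analog_search_cpp(unname(a), unname(b), unname(s),
                           grid$cell_size, threshold_sd, radius_km)
  n_invalid <- sum(res$invalid)
  if (n_invalid > 0)
    message(sprintf("analog_velocity: %d cell(s) with zero/missing interannual SD set to nodata",
                    n_invalid))
  value <- res$distance / elapsed_yr
  field <- exposure_field(value, "analog_velocity", grid,
                          no_analog_mask = res$no_analog,
                          scenario = scenario, esm = esm)
  field$distance_grid <- res$distance
  field$analog_index_grid <- res$analog
  field$elapsed_yr <- elapsed_yr
  field$threshold_sd <- threshold_sd
  field$radius_km <- radius_km
  field
}
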