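#' Define an equal-area analysis grid
#'
#' All computation in climrisk happens on a regular, equal-area projected
#' grid with cell size in kilometres (the continental analyses this package
#' supports are run on grids such as ETRS89-LAEA at 1 km). Geographic
#' (lon/lat) inputs must be reprojected upstream; no great-circle geometry is
#' used anywhere in the package.
#'
#' Cell centers sit at `origin + (index - 0.5) * cell_size`, with row 1 /
#' column 1 at the upper-left corner and y decreasing down rows. Cell extents
#' are half-open, so every point belongs to exactly one cell.
#'
#' @param n_rows,n_cols Grid dimensions. At least 3 each: the spatial
#'   gradient is defined on a 3x3 neighborhood.
#' @param cell_size Cell edge length in km. Must be positive.
#' @param origin Numeric length-2, x/y of the grid's upper-left corner in
#'   projected km.
#' @param crs_label Free-text label for the projection (metadata only).
#' @param nodata Sentinel written to files for missing cells. In memory
#'   missing values are always `NA`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 10, cell_size = 1)
#' cell_centers(g)$x[1:3]
#' @export
grid_spec <- function(n_rows, n_cols, cell_size,
                      origin = c(0, 0),
                      crs_label = "ETRS89-LAEA (km)",
                      nodata = -9999) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 3L || n_cols < 3L)
    stop("grid must be at least 3x3 (spatial gradient needs a 3x3 neighborhood)")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number (km)")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be numeric length 2 (x, y of upper-left corner, km)")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin[1]), origin_y = as.numeric(origin[2]),
         crs_label = as.character(crs_label), nodata = as.numeric(nodata)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g km cell size, origin (%.6g, %.6g), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_label))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d @ %.6g km", x$n_rows, x$n_cols, x$cell_size)
}

grids_identical <- function(a, b, tol = 1e-6) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grids_identical(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 format(a), format(b)))
  invisible(TRUE)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A list with vectors `x` (length `n_cols`, left to right) and `y`
#'   (length `n_rows`, top to bottom, decreasing), in projected km.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

#' Bundle yearly climate layers into a series
#'
#' A `climate_series` holds one value grid per calendar year for a single
#' variable (mean annual near-surface temperature in degrees C, or annual
#' precipitation in mm/yr) over either the baseline or the future period.
#'
#' @param layers Numeric array `n_rows x n_cols x n_years` (or a list of
#'   matrices, one per year). `NA` marks nodata; a cell that is nodata in any
#'   year is treated as nodata throughout downstream climatologies.
#' @param years Integer vector of calendar years, strictly increasing, one
#'   per layer.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param grid The shared [grid_spec()].
#' @param period_label `"baseline"` or `"future"`.
#' @return An object of class `climate_series`.
#' @export
climate_series <- function(layers, years, variable, grid,
                           period_label = c("baseline", "future")) {
  period_label <- match.arg(period_label)
  variable <- match.arg(variable, c("temperature", "precipitation"))
  stopifnot(inherits(grid, "grid_spec"))
  if (is.list(layers))
    layers <- array(unlist(layers, use.names = FALSE),
                    dim = c(nrow(layers[[1]]), ncol(layers[[1]]), length(layers)))
  years <- as.integer(years)
  if (length(dim(layers)) != 3L)
    stop("layers must be a 3-d array (rows x cols x years)")
  if (dim(layers)[3] != length(years))
    stop(sprintf("layer count (%d) does not match number of years (%d)",
                 dim(layers)[3], length(years)))
  if (dim(layers)[1] != grid$n_rows || dim(layers)[2] != grid$n_cols)
    stop("layer dimensions do not match the grid spec")
  if (length(years) > 1L && any(diff(years) <= 0))
    stop("years must be strictly increasing")
  structure(
    list(layers = layers, years = years, variable = variable,
         grid = grid, period_label = period_label),
    class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series> %s, %s %d-%d (%d yr), grid %s\n",
              x$variable, x$period_label, min(x$years), max(x$years),
              length(x$years), format(x$grid)))
  invisible(x)
}

n_years <- function(series) length(series$years)

#' Per-cell climatology (mean and interannual SD)
#'
#' Reduces a yearly series to its per-cell multi-year arithmetic mean and the
#' per-cell sample standard deviation of interannual variability (denominator
#' n - 1). The baseline climatology supplies both the `a` term and the
#' standardizing SD of the magnitude and analog metrics; the future
#' climatology supplies the `b` term.
#'
#' A cell that is nodata in any year is nodata in both output grids.
#'
#' @param series A [climate_series()] with at least 2 years.
#' @return An object of class `climatology` with `mean_grid`, `sd_grid`,
#'   `variable`, `period_label`, `grid`, `years`.
#' @examples
#' g <- grid_spec(3, 3, 1)
#' s <- climate_series(array(rep(1:3, each = 9), c(3, 3, 3)),
#'                     2001:2003, "temperature", g)
#' climatology(s)$mean_grid[1, 1]  # 2
#' @export
climatology <- function(series) {
  stopifnot(inherits(series, "climate_series"))
  ny <- n_years(series)
  if (ny < 2L)
    stop("climatology needs at least 2 years (interannual SD is undefined for 1)")
  L <- series$layers
  any_na <- apply(is.na(L), c(1, 2), any)
  m <- rowMeans(L, dims = 2)
  # sample SD via sum of squared deviations around the per-cell mean
  ss <- rowSums((L - array(m, dim(L)))^2, dims = 2)
  s <- sqrt(ss / (ny - 1))
  m[any_na] <- NA_real_
  s[any_na] <- NA_real_
  structure(
    list(mean_grid = m, sd_grid = s, variable = series$variable,
         period_label = series$period_label, grid = series$grid,
         years = series$years),
    class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology> %s, %s (%d yr), grid %s, mean of means %.4g\n",
              x$variable, x$period_label, length(x$years), format(x$grid),
              mean(x$mean_grid, na.rm = TRUE)))
  invisible(x)
}

#' Construct a per-cell exposure metric surface
#'
#' Container for one of the per-cell exposure metrics. Normally produced by
#' [local_velocity()], [analog_velocity()], [magnitude_sed()] or
#' [combine_abs_sum()] rather than called directly.
#'
#' @param value_grid Numeric matrix of metric values (`NA` = nodata).
#' @param metric One of `"local_velocity"`, `"analog_velocity"`,
#'   `"magnitude"` (and `"outcome"` for synthetic matching outcomes).
#' @param grid The [grid_spec()].
#' @param no_analog_mask Optional logical matrix (analog metric only): cells
#'   with no qualifying analog within the search radius. Such cells are
#'   nodata in `value_grid` but are distinguished from ordinary nodata.
#' @param flags Optional logical matrix of floored/degenerate cells.
#' @param scenario,esm Free-text provenance labels.
#' @return An object of class `exposure_field`.
#' @export
exposure_field <- function(value_grid, metric, grid,
                           no_analog_mask = NULL, flags = NULL,
                           scenario = "unspecified", esm = "unspecified") {
  metric <- match.arg(metric, c("local_velocity", "analog_velocity",
                                "magnitude", "outcome"))
  stopifnot(inherits(grid, "grid_spec"), is.matrix(value_grid))
  if (nrow(value_grid) != grid$n_rows || ncol(value_grid) != grid$n_cols)
    stop("value_grid dimensions do not match grid spec")
  if (!is.null(no_analog_mask)) {
    stopifnot(is.logical(no_analog_mask),
              all(dim(no_analog_mask) == dim(value_grid)))
    if (any(no_analog_mask & !is.na(value_grid)))
      stop("no-analog cells must be nodata in value_grid")
  }
  structure(
    list(value_grid = value_grid, metric = metric, grid = grid,
         no_analog_mask = no_analog_mask, flags = flags,
         scenario = scenario, esm = esm),
    class = "exposure_field")
}

#' @export
print.exposure_field <- function(x, ...) {
  v <- x$value_grid
  cat(sprintf("<exposure_field> %s [%s/%s], grid %s\n", x$metric,
              x$scenario, x$esm, format(x$grid)))
  cat(sprintf("  valid cells: %d/%d; median %.4g; range [%.4g, %.4g]\n",
              sum(!is.na(v)), length(v), stats::median(v, na.rm = TRUE),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  if (!is.null(x$no_analog_mask))
    cat(sprintf("  no-analog cells: %d\n", sum(x$no_analog_mask)))
  invisible(x)
}

#' @export
summary.exposure_field <- function(object, ...) {
  v <- as.vector(object$value_grid)
  out <- c(summary(v[!is.na(v)]),
           n_valid = sum(!is.na(v)), n_total = length(v))
  out
}
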