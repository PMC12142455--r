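#' @title Raster input/output
#' @description
#' Two raster dialects are supported: NetCDF (time x y x x, the primary
#' format, written through `ncdf4` with full grid metadata as attributes) and
#' ESRI ASCII grid (`.asc`, a plain-text single-band interchange format whose
#' header carries the geotransform). Values round-trip bit-exactly through
#' both; in memory nodata is always `NA`, on disk it is the grid's nodata
#' sentinel.
#' @name raster-io
NULL

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path[1]))
  if (ext %in% c("nc", "nc4", "cdf")) return("nc")
  if (ext %in% c("asc", "agr")) return("asc")
  stop(sprintf("cannot infer raster format from extension '.%s' (use .nc or .asc)", ext))
}

#' Write a climate series to disk
#'
#' @param series A [climate_series()].
#' @param path For NetCDF, a single `.nc` path holding the full
#'   time x y x x stack; for ASCII grid, a vector of `.asc` paths, one per
#'   year (a single directory path is also accepted and per-year files are
#'   created inside it).
#' @param format `"nc"` or `"asc"`; inferred from the extension by default.
#' @return The paths written, invisibly.
#' @export
write_series <- function(series, path, format = NULL) {
  stopifnot(inherits(series, "climate_series"))
  if (is.null(format)) {
    format <- if (length(path) == 1L && dir.exists(path)) "asc" else infer_format(path)
  }
  if (format == "nc") {
    write_series_nc(series, path)
  } else {
    if (length(path) == 1L && (dir.exists(path) || !nzchar(tools::file_ext(path)))) {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(path, sprintf("%s_%d.asc", series$variable, series$years))
    }
    if (length(path) != n_years(series))
      stop("need one .asc path per year")
    for (k in seq_along(path))
      write_asc(series$layers[, , k], series$grid, path[k])
    invisible(path)
  }
}

#' Read a climate series from disk
#'
#' All layers must share one geotransform; a layer whose grid differs (cell
#' size, dimensions or origin beyond 1e-6 km) raises an alignment error
#' naming the offending file.
#'
#' @param paths A single NetCDF path, or one `.asc` path per year.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param years Calendar years. For NetCDF, checked against the stored time
#'   coordinate; for ASCII grids, must match the number of files.
#' @param period_label `"baseline"` or `"future"`.
#' @param crs_label Projection label to attach (ASCII grids do not store one).
#' @return A [climate_series()].
#' @export
read_series <- function(paths, variable, years,
                        period_label = c("baseline", "future"),
                        crs_label = "ETRS89-LAEA (km)") {
  period_label <- match.arg(period_label)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  format <- infer_format(paths)
  if (format == "nc") {
    if (length(paths) != 1L) stop("NetCDF series must be a single stack file")
    read_series_nc(paths, variable, years, period_label)
  } else {
    if (length(paths) != length(years))
      stop(sprintf("missing year: %d files for %d years", length(paths), length(years)))
    first <- read_asc(paths[1], crs_label = crs_label)
    grid <- first$grid
    layers <- array(NA_real_, c(grid$n_rows, grid$n_cols, length(years)))
    layers[, , 1] <- first$values
    for (k in seq_along(paths)[-1]) {
      lyr <- read_asc(paths[k], crs_label = crs_label)
      if (!grids_identical(grid, lyr$grid))
        stop(sprintf("layer '%s' is not aligned with '%s' (differing geotransform)",
                     paths[k], paths[1]))
      layers[, , k] <- lyr$values
    }
    # nodata in any year masks the cell across the whole series
    any_na <- apply(is.na(layers), c(1, 2), any)
    layers[array(any_na, dim(layers))] <- NA_real_
    climate_series(layers, years, variable, grid, period_label)
  }
}

write_series_nc <- function(series, path) {
  g <- series$grid
  cc <- cell_centers(g)
  dim_x <- ncdf4::ncdim_def("x", "km", cc$x)
  dim_y <- ncdf4::ncdim_def("y", "km", cc$y)
  dim_t <- ncdf4::ncdim_def("time", "calendar_year", as.double(series$years))
  units <- if (series$variable == "temperature") "degC" else "mm yr-1"
  var <- ncdf4::ncvar_def(series$variable, units, list(dim_x, dim_y, dim_t),
                          missval = g$nodata, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  # ncdf4 expects x fastest: transpose each layer to [x, y, t]
  arr <- aperm(series$layers, c(2, 1, 3))
  ncdf4::ncvar_put(nc, var, arr)
  ncdf4::ncatt_put(nc, 0, "crs_label", g$crs_label)
  ncdf4::ncatt_put(nc, 0, "cell_size_km", g$cell_size)
  ncdf4::ncatt_put(nc, 0, "origin_x_km", g$origin_x)
  ncdf4::ncatt_put(nc, 0, "origin_y_km", g$origin_y)
  ncdf4::ncatt_put(nc, 0, "period_label", series$period_label)
  invisible(path)
}

read_series_nc <- function(path, variable, years, period_label) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop(sprintf("variable '%s' not present in '%s'", variable, path))
  stored_years <- as.integer(ncdf4::ncvar_get(nc, "time"))
  if (length(stored_years) != length(years))
    stop(sprintf("missing year: stack has %d layers for %d requested years",
                 length(stored_years), length(years)))
  if (!all(stored_years == as.integer(years)))
    stop("stored years do not match requested years")
  arr <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  arr <- aperm(arr, c(2, 1, 3))
  att <- function(name) ncdf4::ncatt_get(nc, 0, name)$value
  grid <- grid_spec(dim(arr)[1], dim(arr)[2], att("cell_size_km"),
                    origin = c(att("origin_x_km"), att("origin_y_km")),
                    crs_label = att("crs_label"),
                    nodata = nc$var[[variable]]$missval)
  any_na <- apply(is.na(arr), c(1, 2), any)
  arr[array(any_na, dim(arr))] <- NA_real_
  climate_series(arr, years, variable, grid, period_label)
}

write_asc <- function(values, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  yll <- grid$origin_y - grid$n_rows * grid$cell_size
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10f", grid$origin_x),
    sprintf("yllcorner %.10f", yll),
    sprintf("cellsize %.10f", grid$cell_size),
    sprintf("NODATA_value %s", formatC(grid$nodata, format = "g", digits = 17))
  ), con)
  v <- values
  v[is.na(v)] <- grid$nodata
  writeLines(apply(v, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

read_asc <- function(path, crs_label = "ETRS89-LAEA (km)") {
  header <- readLines(path, n = 6)
  hv <- function(i) strsplit(trimws(header[i]), "\\s+")[[1]][2]
  n_cols <- as.integer(hv(1)); n_rows <- as.integer(hv(2))
  xll <- as.numeric(hv(3)); yll <- as.numeric(hv(4))
  cellsize <- as.numeric(hv(5)); nodata <- as.numeric(hv(6))
  body <- scan(path, skip = 6, quiet = TRUE)
  if (length(body) != n_rows * n_cols)
    stop(sprintf("'%s': expected %d values, found %d", path, n_rows * n_cols, length(body)))
  values <- matrix(body, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  values[values == nodata] <- NA_real_
  grid <- grid_spec(n_rows, n_cols, cellsize,
                    origin = c(xll, yll + n_rows * cellsize),
                    crs_label = crs_label, nodata = nodata)
  list(values = values, grid = grid)
}

#' Write an exposure field to disk
#'
#' NetCDF output stores the metric values plus, when present, the no-analog
#' mask as a companion 0/1 variable and metric/scenario/ESM provenance
#' attributes. ASCII-grid output writes the values to `path` and the mask to
#' `<path stem>_noanalog.asc`.
#'
#' @param field An [exposure_field()].
#' @param path Output path (`.nc` or `.asc`).
#' @param format Overrides extension-based inference.
#' @return Paths written, invisibly.
#' @export
write_field <- function(field, path, format = NULL) {
  stopifnot(inherits(field, "exposure_field"))
  if (is.null(format)) format <- infer_format(path)
  g <- field$grid
  if (format == "nc") {
    cc <- cell_centers(g)
    dim_x <- ncdf4::ncdim_def("x", "km", cc$x)
    dim_y <- ncdf4::ncdim_def("y", "km", cc$y)
    units <- if (field$metric == "magnitude") "1" else "km yr-1"
    vars <- list(ncdf4::ncvar_def("value", units, list(dim_x, dim_y),
                                  missval = g$nodata, prec = "double"))
    if (!is.null(field$no_analog_mask))
      vars <- c(vars, list(ncdf4::ncvar_def("no_analog", "1", list(dim_x, dim_y),
                                            missval = -1, prec = "integer")))
    nc <- ncdf4::nc_create(path, vars)
    on.exit(ncdf4::nc_close(nc))
    ncdf4::ncvar_put(nc, vars[[1]], t(field$value_grid))
    if (!is.null(field$no_analog_mask))
      ncdf4::ncvar_put(nc, vars[[2]], t(field$no_analog_mask * 1L))
    ncdf4::ncatt_put(nc, 0, "metric", field$metric)
    ncdf4::ncatt_put(nc, 0, "scenario", field$scenario)
    ncdf4::ncatt_put(nc, 0, "esm", field$esm)
    ncdf4::ncatt_put(nc, 0, "crs_label", g$crs_label)
    ncdf4::ncatt_put(nc, 0, "cell_size_km", g$cell_size)
    ncdf4::ncatt_put(nc, 0, "origin_x_km", g$origin_x)
    ncdf4::ncatt_put(nc, 0, "origin_y_km", g$origin_y)
    invisible(path)
  } else {
    write_asc(field$value_grid, g, path)
    paths <- path
    if (!is.null(field$no_analog_mask)) {
      mask_path <- sub("\\.asc$", "_noanalog.asc", path)
      write_asc(field$no_analog_mask * 1, g, mask_path)
      paths <- c(paths, mask_path)
    }
    invisible(paths)
  }
}

#' Read an exposure field written by [write_field()]
#'
#' @param path Path to a `.nc` or `.asc` file.
#' @param metric Metric label; for NetCDF taken from the file when omitted.
#' @param crs_label Attached to ASCII-grid reads.
#' @return An [exposure_field()].
#' @export
read_field <- function(path, metric = NULL, crs_label = "ETRS89-LAEA (km)") {
  format <- infer_format(path)
  if (format == "nc") {
    nc <- ncdf4::nc_open(path)
    on.exit(ncdf4::nc_close(nc))
    att <- function(name) ncdf4::ncatt_get(nc, 0, name)$value
    values <- t(ncdf4::ncvar_get(nc, "value"))
    grid <- grid_spec(nrow(values), ncol(values), att("cell_size_km"),
                      origin = c(att("origin_x_km"), att("origin_y_km")),
                      crs_label = att("crs_label"),
                      nodata = nc$var[["value"]]$missval)
    mask <- NULL
    if ("no_analog" %in% names(nc$var))
      mask <- t(ncdf4::ncvar_get(nc, "no_analog")) == 1
    exposure_field(values, if (is.null(metric)) att("metric") else metric, grid,
                   no_analog_mask = mask, scenario = att("scenario"), esm = att("esm"))
  } else {
    r <- read_asc(path, crs_label = crs_label)
    mask_path <- sub("\\.asc$", "_noanalog.asc", path)
    mask <- NULL
    if (file.exists(mask_path)) mask <- read_asc(mask_path)$values == 1
    exposure_field(r$values, if (is.null(metric)) "magnitude" else metric,
                   r$grid, no_analog_mask = mask)
  }
}
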