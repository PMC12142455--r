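#' @title Protected-area polygon sets
#' @description
#' Protected areas are represented as a `pa_set`: a list of planar geometries
#' (axis-aligned rectangles, discs, or arbitrary simple polygons, all in
#' projected km) plus an attribute table with identifier, biogeographic
#' region label, analytic area (km^2) and the equivalent-circle diameter
#' `2*sqrt(A/pi)` used by the residence-time metric. Input polygons are
#' assumed already dissolved, terrestrial and non-overlapping (the upstream
#' cleaning contract); no de-duplication is attempted here.
#' @name pa-polygons
NULL

geom_disc <- function(center, radius) {
  stopifnot(radius > 0)
  list(type = "disc", center = as.numeric(center), radius = as.numeric(radius))
}

geom_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  list(type = "polygon",
       coords = cbind(x = c(xmin, xmax, xmax, xmin),
                      y = c(ymin, ymin, ymax, ymax)))
}

geom_polygon <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 3)
  # drop an explicitly closed last vertex
  if (all(coords[1, ] == coords[nrow(coords), ])) coords <- coords[-nrow(coords), ]
  list(type = "polygon", coords = coords)
}

geom_area <- function(geom) {
  if (geom$type == "disc") return(pi * geom$radius^2)
  xy <- geom$coords
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

geom_bbox <- function(geom) {
  if (geom$type == "disc")
    c(xmin = geom$center[1] - geom$radius, ymin = geom$center[2] - geom$radius,
      xmax = geom$center[1] + geom$radius, ymax = geom$center[2] + geom$radius)
  else
    c(xmin = min(geom$coords[, 1]), ymin = min(geom$coords[, 2]),
      xmax = max(geom$coords[, 1]), ymax = max(geom$coords[, 2]))
}

points_in_geom <- function(geom, px, py) {
  if (geom$type == "disc") {
    (px - geom$center[1])^2 + (py - geom$center[2])^2 <= geom$radius^2
  } else {
    sp::point.in.polygon(px, py, geom$coords[, 1], geom$coords[, 2]) > 0
  }
}

#' Assemble a protected-area set
#'
#' @param geoms List of geometries from `geom_disc()`, `geom_rect()` or
#'   `geom_polygon()` (all coordinates in projected km).
#' @param polygon_id Character or integer identifiers, unique.
#' @param region Biogeographic region label per polygon (matching and
#'   reporting are stratified by this label).
#' @return A `pa_set`: list with `geoms` and a data frame `table`
#'   (`polygon_id`, `region`, `area_km2`, `diameter_km`).
#' @examples
#' pas <- pa_set(list(geom_disc(c(50, -50), 10)), "PA1", "Boreal")
#' pas$table$diameter_km  # 20
#' @export
pa_set <- function(geoms, polygon_id = NULL, region = "all") {
  if (length(geoms) == 0L) {
    return(structure(list(
      geoms = list(),
      table = data.frame(polygon_id = character(), region = character(),
                         area_km2 = numeric(), diameter_km = numeric(),
                         stringsAsFactors = FALSE)), class = "pa_set"))
  }
  if (is.null(polygon_id)) polygon_id <- sprintf("PA%04d", seq_along(geoms))
  polygon_id <- as.character(polygon_id)
  if (anyDuplicated(polygon_id)) stop("polygon_id must be unique")
  region <- rep_len(as.character(region), length(geoms))
  area <- vapply(geoms, geom_area, numeric(1))
  if (any(area <= 0)) stop("all polygon areas must be positive")
  structure(list(
    geoms = geoms,
    table = data.frame(polygon_id = polygon_id, region = region,
                       area_km2 = area, diameter_km = 2 * sqrt(area / pi),
                       stringsAsFactors = FALSE)), class = "pa_set")
}

#' @export
print.pa_set <- function(x, ...) {
  cat(sprintf("<pa_set> %d polygons", nrow(x$table)))
  if (nrow(x$table)) {
    cat(sprintf(", areas %.4g-%.4g km2, %d region(s)",
                min(x$table$area_km2), max(x$table$area_km2),
                length(unique(x$table$region))))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.pa_set <- function(x) nrow(x$table)

#' Indices of grid cells whose centers fall inside a geometry
#'
#' Cell membership everywhere in the package uses cell-CENTER containment,
#' which keeps zonal medians unambiguous at the native cell scale.
#'
#' @param grid A [grid_spec()].
#' @param geom One geometry from a `pa_set`.
#' @return Integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
cells_in_geom <- function(grid, geom) {
  cc <- cell_centers(grid)
  bb <- geom_bbox(geom)
  cols <- which(cc$x >= bb["xmin"] - grid$cell_size & cc$x <= bb["xmax"] + grid$cell_size)
  rows <- which(cc$y >= bb["ymin"] - grid$cell_size & cc$y <= bb["ymax"] + grid$cell_size)
  if (!length(rows) || !length(cols))
    return(cbind(row = integer(), col = integer()))
  gr <- expand.grid(row = rows, col = cols)
  inside <- points_in_geom(geom, cc$x[gr$col], cc$y[gr$row])
  cbind(row = gr$row[inside], col = gr$col[inside])
}

#' Per-cell protected fraction from a polygon set
#'
#' Approximates the fraction of each cell's area covered by the union of the
#' polygons by regular subsampling (`subsamples^2` points per cell). With
#' non-overlapping polygons the union is a plain maximum.
#'
#' @param grid A [grid_spec()].
#' @param pas A [pa_set()].
#' @param subsamples Subsample points per cell edge (default 4, i.e. 16
#'   points per cell, 1/16 fraction resolution).
#' @return Numeric matrix of fractions in `[0, 1]`.
#' @export
protection_fraction <- function(grid, pas, subsamples = 4L) {
  stopifnot(inherits(pas, "pa_set"), subsamples >= 1L)
  frac <- matrix(0, grid$n_rows, grid$n_cols)
  if (!length(pas$geoms)) return(frac)
  k <- as.integer(subsamples)
  off <- (seq_len(k) - 0.5) / k  # sub-cell offsets in (0, 1)
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  for (oy in off) for (ox in off) {
    px_cols <- grid$origin_x + (seq_len(grid$n_cols) - 1 + ox) * grid$cell_size
    py_rows <- grid$origin_y - (seq_len(grid$n_rows) - 1 + oy) * grid$cell_size
    covered <- matrix(FALSE, grid$n_rows, grid$n_cols)
    for (geom in pas$geoms) {
      bb <- geom_bbox(geom)
      cols <- which(px_cols >= bb["xmin"] & px_cols <= bb["xmax"])
      rows <- which(py_rows >= bb["ymin"] & py_rows <= bb["ymax"])
      if (!length(rows) || !length(cols)) next
      gr <- expand.grid(row = rows, col = cols)
      inside <- points_in_geom(geom, px_cols[gr$col], py_rows[gr$row])
      covered[cbind(gr$row[inside], gr$col[inside])] <- TRUE
    }
    counts <- counts + covered
  }
  counts / (k * k)
}

disc_ring <- function(center, radius, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Write a protected-area set as GeoJSON
#'
#' Discs are written as 72-gon rings with their analytic center and radius
#' preserved in feature properties, so [read_pa_geojson()] restores exact
#' areas.
#'
#' @param pas A [pa_set()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_pa_geojson <- function(pas, path) {
  stopifnot(inherits(pas, "pa_set"))
  features <- lapply(seq_along(pas$geoms), function(i) {
    geom <- pas$geoms[[i]]
    props <- list(polygon_id = pas$table$polygon_id[i],
                  region = pas$table$region[i])
    if (geom$type == "disc") {
      props$pa_type <- "disc"
      props$center_x <- geom$center[1]
      props$center_y <- geom$center[2]
      props$radius_km <- geom$radius
      ring <- disc_ring(geom$center, geom$radius)
    } else {
      props$pa_type <- "polygon"
      ring <- geom$coords
    }
    ring <- rbind(ring, ring[1, , drop = FALSE])  # closed ring
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring))))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a protected-area set from GeoJSON
#'
#' @param path A `.geojson` FeatureCollection of Polygon features; features
#'   carrying `pa_type = "disc"` properties are restored as analytic discs.
#' @return A [pa_set()].
#' @export
read_pa_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  geoms <- list(); ids <- character(); regions <- character()
  for (f in fc$features) {
    p <- f$properties
    if (identical(p$pa_type, "disc")) {
      g <- geom_disc(c(p$center_x, p$center_y), p$radius_km)
    } else {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                    function(v) unlist(v)))
      g <- geom_polygon(ring)
    }
    geoms <- c(geoms, list(g))
    ids <- c(ids, as.character(p$polygon_id))
    regions <- c(regions, if (is.null(p$region)) "all" else as.character(p$region))
  }
  pa_set(geoms, ids, regions)
}
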