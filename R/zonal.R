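#' @title Polygon-level exposure summaries
#' @description
#' Zonal medians of metric surfaces over protected-area polygons
#' (cell-center containment), climate residence time of polygons, and
#' species-level exposure over occupied sites.
#' @name zonal-exposure
NULL

field_values <- function(field) {
  if (inherits(field, "exposure_field")) field$value_grid
  else if (inherits(field, "ensemble_field")) field$mean_grid
  else if (is.matrix(field)) field
  else stop("expected an exposure_field, ensemble_field, or matrix")
}

field_grid <- function(field, grid = NULL) {
  if (inherits(field, c("exposure_field", "ensemble_field"))) field$grid
  else if (!is.null(grid)) grid
  else stop("a bare matrix field needs an explicit grid")
}

#' Zonal median of a metric surface per polygon
#'
#' The median is taken over the cells whose centers fall inside each
#' polygon. A polygon covering no cell center gets `NA` with a warning;
#' an empty polygon set is an error.
#'
#' @param field An [exposure_field()], `ensemble_field`, or matrix.
#' @param pas A [pa_set()].
#' @param grid Required when `field` is a bare matrix.
#' @param fun Summary function (default [stats::median()]; zonal means use
#'   `fun = mean`). `NA` cells are dropped.
#' @return Named numeric vector, one value per polygon.
#' @export
zonal_median <- function(field, pas, grid = NULL, fun = stats::median) {
  stopifnot(inherits(pas, "pa_set"))
  if (!length(pas$geoms)) stop("empty polygon set")
  values <- field_values(field)
  grid <- field_grid(field, grid)
  out <- vapply(seq_along(pas$geoms), function(i) {
    idx <- cells_in_geom(grid, pas$geoms[[i]])
    if (nrow(idx) == 0L) return(NA_real_)
    v <- values[idx]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    fun(v)
  }, numeric(1))
  names(out) <- pas$table$polygon_id
  if (anyNA(out))
    warning(sprintf("%d polygon(s) cover no valid cell center; returned NA",
                    sum(is.na(out))))
  out
}

#' Climate residence time of a polygon
#'
#' Years until current climatic conditions are displaced out of a polygon:
#' the polygon's equivalent-circle diameter `2*sqrt(A/pi)` divided by the
#' mean climate velocity inside it. Velocities below `velocity_floor` are
#' floored to avoid infinite times; affected entries carry a `floored`
#' attribute.
#'
#' @param area_km2 Polygon area(s), km^2, > 0.
#' @param mean_velocity_kmyr Mean within-polygon climate velocity, km/yr,
#'   >= 0.
#' @param velocity_floor Minimum velocity (default 0.01 km/yr).
#' @return Residence time(s) in years, with attribute `floored` (logical).
#' @examples
#' residence_time(pi, 1)      # diameter 2 km at 1 km/yr -> 2 yr
#' residence_time(100 * pi, 5) # 4 yr
#' @export
residence_time <- function(area_km2, mean_velocity_kmyr, velocity_floor = 0.01) {
  if (any(!is.na(area_km2) & area_km2 <= 0))
    stop("polygon area must be positive")
  if (any(!is.na(mean_velocity_kmyr) & mean_velocity_kmyr < 0))
    stop("mean velocity must be non-negative")
  stopifnot(velocity_floor > 0)
  floored <- !is.na(mean_velocity_kmyr) & mean_velocity_kmyr < velocity_floor
  rt <- 2 * sqrt(area_km2 / pi) / pmax(mean_velocity_kmyr, velocity_floor)
  attr(rt, "floored") <- floored
  rt
}

#' Per-polygon exposure table
#'
#' The per-protected-area deliverable: zonal medians of each supplied metric
#' surface, the polygon-mean combined local velocity, and the residence
#' time derived from it.
#'
#' @param pas A [pa_set()].
#' @param fields Named list of metric surfaces ([exposure_field()] /
#'   `ensemble_field`); names become `median_<name>` columns.
#' @param velocity_field Surface whose polygon MEAN supplies the `gV` term
#'   of residence time; by default the combined (absolute-sum) local
#'   velocity entry of `fields` (named `"local_velocity"`), configurable to
#'   e.g. a temperature-only field.
#' @param velocity_floor Passed to [residence_time()].
#' @return A data frame: `polygon_id`, `region`, `area_km2`, `diameter_km`,
#'   one `median_*` column per field, `mean_local_velocity`,
#'   `residence_time_yr`, `rt_floored`.
#' @export
pa_exposure_table <- function(pas, fields,
                              velocity_field = fields[["local_velocity"]],
                              velocity_floor = 0.01) {
  stopifnot(inherits(pas, "pa_set"), length(fields) >= 1)
  if (is.null(velocity_field))
    stop("velocity_field is required (no 'local_velocity' entry in fields)")
  tab <- pas$table
  for (nm in names(fields))
    tab[[paste0("median_", nm)]] <- unname(zonal_median(fields[[nm]], pas))
  gv <- zonal_median(velocity_field, pas, fun = mean)
  rt <- residence_time(tab$area_km2, unname(gv), velocity_floor)
  tab$mean_local_velocity <- unname(gv)
  tab$residence_time_yr <- as.numeric(rt)
  tab$rt_floored <- attr(rt, "floored")
  tab
}

#' Species-level exposure over occupied sites
#'
#' Per species, the median of site-level metric values over the sites it
#' occupies; when site areas are supplied an area-weighted mean
#' `sum(v_s * A_s) / sum(A_s)` is added (the variant used for species whose
#' range overlap with the network is known).
#'
#' @param occ An `occurrence_table` from [make_species_occurrences()] (or a
#'   compatible list with `incidence`, `species_id`, `site_ids`,
#'   `range_overlap`).
#' @param site_values Data frame with a `site_id` column plus one numeric
#'   column per metric (e.g. the output of [pa_exposure_table()] renamed),
#'   or a named numeric vector for a single metric.
#' @param site_areas Optional named numeric vector of site areas (km^2).
#' @return A data frame: `species_id`, `n_sites`, `median_<metric>` per
#'   metric, `weighted_<metric>` when areas are given, and `range_overlap`
#'   when present.
#' @export
species_exposure <- function(occ, site_values, site_areas = NULL) {
  if (is.numeric(site_values) && !is.null(names(site_values)))
    site_values <- data.frame(site_id = names(site_values),
                              value = unname(site_values),
                              stringsAsFactors = FALSE)
  stopifnot(is.data.frame(site_values), "site_id" %in% names(site_values))
  metrics <- setdiff(names(site_values), "site_id")
  orphan <- setdiff(occ$site_ids, site_values$site_id)
  if (length(orphan))
    stop("occupied site id(s) missing from site_values: ",
         paste(orphan, collapse = ", "))
  site_values <- site_values[match(occ$site_ids, site_values$site_id), , drop = FALSE]
  if (!is.null(site_areas)) {
    if (is.null(names(site_areas)))
      stop("site_areas must be named by site_id")
    missing_area <- setdiff(occ$site_ids, names(site_areas))
    if (length(missing_area))
      stop("site id(s) missing from site_areas: ",
           paste(missing_area, collapse = ", "))
    areas <- site_areas[occ$site_ids]
  }
  n_sp <- nrow(occ$incidence)
  out <- data.frame(species_id = occ$species_id,
                    n_sites = rowSums(occ$incidence),
                    stringsAsFactors = FALSE)
  for (m in metrics) {
    v <- site_values[[m]]
    out[[paste0("median_", m)]] <- vapply(seq_len(n_sp), function(i) {
      vi <- v[occ$incidence[i, ]]
      stats::median(vi, na.rm = TRUE)
    }, numeric(1))
    if (!is.null(site_areas)) {
      out[[paste0("weighted_", m)]] <- vapply(seq_len(n_sp), function(i) {
        sel <- occ$incidence[i, ]
        vi <- v[sel]; ai <- areas[sel]
        ok <- !is.na(vi)
        if (!any(ok)) return(NA_real_)
        sum(vi[ok] * ai[ok]) / sum(ai[ok])
      }, numeric(1))
    }
  }
  if (!is.null(occ$range_overlap)) out$range_overlap <- occ$range_overlap
  out
}
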