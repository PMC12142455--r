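#' @title Quartile hotspots, coldspots and multi-metric overlay
#' @description
#' Hotspots are cells in the last quartile of an ensemble exposure metric,
#' coldspots cells in the first quartile; joint coldspots across all metrics
#' proxy climate refugia. The overlay codes each cell by the subset of
#' metrics for which it is a hotspot.
#' @name hotspot-overlay
NULL

#' First/last-quartile masks of an exposure surface
#'
#' Thresholds are the empirical 25th and 75th percentiles over valid cells
#' (linear interpolation, [stats::quantile()] type 7). A cell is a hotspot
#' when strictly above Q3 and a coldspot when strictly below Q1; ties at a
#' threshold belong to neither mask. The masks are therefore invariant to
#' any strictly monotone transform of the metric.
#'
#' @param field An [exposure_field()], `ensemble_field` or matrix with at
#'   least 4 valid cells.
#' @return A `quartile_masks` object: list with logical `coldspot` and
#'   `hotspot` matrices (`FALSE` on nodata cells), thresholds `q1`, `q3`,
#'   and `valid` mask.
#' @examples
#' qm <- quartile_masks(matrix(1:100, 10, 10))
#' sum(qm$hotspot)  # 25
#' @export
quartile_masks <- function(field) {
  values <- field_values(field)
  valid <- !is.na(values)
  if (sum(valid) < 4L) stop("need at least 4 valid cells for quartiles")
  q <- stats::quantile(values[valid], c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] == q[2]) {
    warning("constant (or near-constant) field: empty quartile masks")
  }
  hot <- valid & values > q[2]
  cold <- valid & values < q[1]
  hot[is.na(hot)] <- FALSE
  cold[is.na(cold)] <- FALSE
  structure(list(coldspot = cold, hotspot = hot, q1 = q[1], q3 = q[2],
                 valid = valid),
            class = "quartile_masks")
}

overlay_code_table <- function() {
  data.frame(
    code = c(0:7, 8L, 9L),
    label = c("none", "local", "analog", "local+analog", "magnitude",
              "local+magnitude", "analog+magnitude",
              "local+analog+magnitude", "joint_coldspot", "no_analog"),
    stringsAsFactors = FALSE)
}

#' Multi-metric hotspot/coldspot overlay
#'
#' Combines the per-metric quartile masks into one categorical surface.
#' Codes 0-7 give the subset of metrics for which the cell is a hotspot
#' (bit 1 = local velocity, bit 2 = analog velocity, bit 4 = magnitude);
#' code 8 marks joint coldspots (all three metrics in their first
#' quartile), and code 9 marks cells with no climate analog within the
#' search radius, which are blanked out of the analog metric. Cells invalid
#' in any metric are `NA`.
#'
#' @param masks Named list with elements `local`, `analog`, `magnitude`,
#'   each a [quartile_masks()] object on the same grid.
#' @param no_analog Optional logical matrix of no-analog cells.
#' @param grid Optional [grid_spec()] carried through to outputs.
#' @return An `overlay_field`: list with integer `code_grid`, the code
#'   table, the input masks and `no_analog`.
#' @export
overlay_code <- function(masks, no_analog = NULL, grid = NULL) {
  need <- c("local", "analog", "magnitude")
  if (!all(need %in% names(masks)))
    stop("masks must be a named list with elements local, analog, magnitude")
  dims <- dim(masks$local$hotspot)
  for (m in need) {
    stopifnot(inherits(masks[[m]], "quartile_masks"))
    if (!all(dim(masks[[m]]$hotspot) == dims))
      stop("grid mismatch between metric masks")
  }
  code <- masks$local$hotspot * 1L + masks$analog$hotspot * 2L +
    masks$magnitude$hotspot * 4L
  joint_cold <- masks$local$coldspot & masks$analog$coldspot &
    masks$magnitude$coldspot
  code[joint_cold] <- 8L
  valid <- masks$local$valid & masks$analog$valid & masks$magnitude$valid
  code[!valid] <- NA_integer_
  if (!is.null(no_analog)) {
    stopifnot(all(dim(no_analog) == dims))
    code[no_analog] <- 9L
  }
  structure(list(code_grid = code, code_table = overlay_code_table(),
                 masks = masks, no_analog = no_analog, grid = grid),
            class = "overlay_field")
}

#' @export
print.overlay_field <- function(x, ...) {
  counts <- table(factor(x$code_grid, levels = x$code_table$code,
                         labels = x$code_table$label))
  cat("<overlay_field> cell counts by category:\n")
  print(counts)
  invisible(x)
}

#' Protected-area coverage of hotspot/coldspot categories
#'
#' Reports exposure-category coverage at two levels: (i) the percentage of
#' protected CELLS (protection fraction above the treated threshold) in
#' each overlay category, and (ii) the percentage of protected-area
#' POLYGONS overlapping each category. A polygon "overlaps a hotspot" if at
#' least one of its cells is a hotspot of that metric, but counts as "in a
#' coldspot" only if all of its cells are joint coldspots - mirroring the
#' asymmetry between refugia (uniformly low exposure) and risk (any high
#' exposure).
#'
#' @param overlay An [overlay_code()] result.
#' @param protection Protection-fraction matrix (from
#'   [protection_fraction()] or a synthetic landscape).
#' @param pas Optional [pa_set()] for the polygon-level report.
#' @param grid [grid_spec()]; needed for the polygon-level report when the
#'   overlay carries none.
#' @param treated_threshold Protection fraction above which a cell counts
#'   as protected (default 0.5).
#' @return A list with data frames `cells` (category, n, pct over protected
#'   cells) and, when `pas` is given, `polygons` (category, n, pct of
#'   polygons); `NULL` polygons slot otherwise.
#' @export
pa_coverage <- function(overlay, protection, pas = NULL, grid = NULL,
                        treated_threshold = 0.5) {
  stopifnot(inherits(overlay, "overlay_field"))
  code <- overlay$code_grid
  stopifnot(all(dim(protection) == dim(code)))
  prot <- protection > treated_threshold
  n_prot <- sum(prot, na.rm = TRUE)
  if (n_prot == 0L) {
    warning("no protected cells above the threshold; empty coverage report")
    return(list(cells = data.frame(category = character(), n = integer(),
                                   pct = numeric(), stringsAsFactors = FALSE),
                polygons = NULL))
  }
  ct <- overlay$code_table
  pc <- code[prot]
  counts <- vapply(ct$code, function(k) sum(pc == k, na.rm = TRUE), integer(1))
  extra <- c(
    hot_local = sum(pc %in% c(1L, 3L, 5L, 7L), na.rm = TRUE),
    hot_analog = sum(pc %in% c(2L, 3L, 6L, 7L), na.rm = TRUE),
    hot_magnitude = sum(pc %in% c(4L, 5L, 6L, 7L), na.rm = TRUE),
    hot_any = sum(pc %in% 1:7, na.rm = TRUE),
    hot_local_or_magnitude = sum(pc %in% c(1L, 3L, 4L, 5L, 7L), na.rm = TRUE))
  cells <- data.frame(
    category = c(ct$label, names(extra)),
    n = c(counts, unname(extra)),
    pct = 100 * c(counts, unname(extra)) / n_prot,
    stringsAsFactors = FALSE)

  polygons <- NULL
  if (!is.null(pas) && length(pas$geoms)) {
    g <- if (!is.null(overlay$grid)) overlay$grid else grid
    if (is.null(g)) stop("polygon-level coverage needs a grid_spec")
    per_pa <- lapply(pas$geoms, function(geom) cells_in_geom(g, geom))
    any_hot <- function(metric_bits) vapply(per_pa, function(idx) {
      if (nrow(idx) == 0L) return(NA)
      any(code[idx] %in% metric_bits, na.rm = TRUE)
    }, logical(1))
    all_cold <- vapply(per_pa, function(idx) {
      if (nrow(idx) == 0L) return(NA)
      v <- code[idx]
      length(v) > 0 && all(!is.na(v)) && all(v == 8L)
    }, logical(1))
    rows <- list(
      hot_local = any_hot(c(1L, 3L, 5L, 7L)),
      hot_analog = any_hot(c(2L, 3L, 6L, 7L)),
      hot_magnitude = any_hot(c(4L, 5L, 6L, 7L)),
      hot_any = any_hot(1:7),
      hot_local_or_magnitude = any_hot(c(1L, 3L, 4L, 5L, 7L)),
      all_cold = all_cold)
    n_pa <- length(per_pa)
    polygons <- data.frame(
      category = names(rows),
      n = vapply(rows, function(v) sum(v, na.rm = TRUE), integer(1)),
      pct = vapply(rows, function(v) 100 * sum(v, na.rm = TRUE) / n_pa, numeric(1)),
      stringsAsFactors = FALSE)
    rownames(polygons) <- NULL
  }
  list(cells = cells, polygons = polygons)
}
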