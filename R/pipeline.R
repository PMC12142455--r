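#' @title End-to-end pipeline
#' @description
#' Configuration, orchestration and report generation: from (synthetic or
#' user-supplied) yearly climate series to metric rasters, ensemble
#' summaries, hotspot overlays, polygon tables, matched-pairs reports and
#' species exposure tables, in one deterministic, seeded run.
#' @name pipeline
NULL

#' Build and validate a pipeline configuration
#'
#' All tunable parameters of the analysis in one validated object. The
#' defaults define a compact synthetic study system: a 48 x 48 grid of
#' 10 km cells, temperature and precipitation series for 1981-2010 and
#' 2041-2070, one scenario with three pseudo-ESM members that differ in
#' their future temperature trend, 12 protected-area polygons and 40
#' species.
#'
#' @param seed Integer master seed; every stochastic stage derives its
#'   stream from it.
#' @param n_rows,n_cols,cell_size_km Grid geometry.
#' @param years_baseline,years_future Calendar years of the two periods.
#' @param scenario Scenario label.
#' @param esm_trends Named numeric vector: future temperature trend
#'   (degC/yr) per pseudo-ESM member.
#' @param temperature,precipitation Lists of planar-series parameters
#'   (`base`, `gradient`, `axis`, `trend`, `noise_sd`).
#' @param threshold_sd,radius_km,elapsed_yr Analog-search parameters
#'   (dissimilarity threshold in SD units, search radius, years between
#'   period midpoints).
#' @param gradient_floor Minimum spatial gradient (units/km) for the local
#'   velocity denominator.
#' @param caliper_sd Matching caliper in SD-of-scores units.
#' @param velocity_floor Minimum velocity (km/yr) for residence time.
#' @param n_polygons,area_range,n_regions,marginal_frac Protected-landscape
#'   parameters.
#' @param n_species,occupancy_prob Species-occurrence parameters.
#' @param log_level `"info"` (stage timers on stderr) or `"quiet"`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_rows = 48L, n_cols = 48L, cell_size_km = 10,
                            years_baseline = 1981:2010,
                            years_future = 2041:2070,
                            scenario = "ssp126",
                            esm_trends = c(esm1 = 0.04, esm2 = 0.05, esm3 = 0.06),
                            temperature = list(base = 8, gradient = 0.02,
                                               axis = "x", trend = 0.03,
                                               noise_sd = 0.4),
                            precipitation = list(base = 800, gradient = 1.0,
                                                 axis = "y", trend = -1.5,
                                                 noise_sd = 40),
                            threshold_sd = 1.5, radius_km = 1500,
                            elapsed_yr = 60, gradient_floor = 1e-4,
                            caliper_sd = 0.25, velocity_floor = 0.01,
                            n_polygons = 12L, area_range = c(100, 2000),
                            n_regions = 2L, marginal_frac = 0.1,
                            n_species = 40L, occupancy_prob = 0.3,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  cfg <- list(seed = as.integer(seed), n_rows = as.integer(n_rows),
              n_cols = as.integer(n_cols), cell_size_km = cell_size_km,
              years_baseline = years_baseline, years_future = years_future,
              scenario = scenario, esm_trends = esm_trends,
              temperature = temperature, precipitation = precipitation,
              threshold_sd = threshold_sd, radius_km = radius_km,
              elapsed_yr = elapsed_yr, gradient_floor = gradient_floor,
              caliper_sd = caliper_sd, velocity_floor = velocity_floor,
              n_polygons = as.integer(n_polygons), area_range = area_range,
              n_regions = as.integer(n_regions), marginal_frac = marginal_frac,
              n_species = as.integer(n_species),
              occupancy_prob = occupancy_prob, log_level = log_level)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$n_rows >= 3 && cfg$n_cols >= 3, "grid must be at least 3x3")
  chk(cfg$cell_size_km > 0, "cell_size_km must be positive")
  chk(cfg$threshold_sd > 0, "threshold_sd must be positive")
  chk(cfg$radius_km > 0, "radius_km must be positive")
  chk(cfg$elapsed_yr > 0, "elapsed_yr must be positive")
  chk(cfg$gradient_floor > 0, "gradient_floor must be positive")
  chk(cfg$caliper_sd > 0, "caliper_sd must be positive")
  chk(cfg$velocity_floor > 0, "velocity_floor must be positive")
  chk(length(cfg$years_baseline) >= 2 && length(cfg$years_future) >= 2,
      "each period needs at least 2 years")
  chk(length(cfg$esm_trends) >= 2, "need at least 2 ensemble members")
  chk(cfg$occupancy_prob >= 0 && cfg$occupancy_prob <= 1,
      "occupancy_prob must lie in [0, 1]")
  chk(cfg$n_polygons >= 0, "n_polygons must be non-negative")
  invisible(TRUE)
}

stage_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info"))
    message(sprintf("[climrisk %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(fmt, ...))
  invisible(NULL)
}

write_csv_manifest <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# climrisk manifest %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full exposure pipeline on a synthetic study system
#'
#' Generates the seeded synthetic inputs, computes all per-cell metrics for
#' every ensemble member, ensembles them, classifies hotspots/coldspots,
#' summarizes polygons (including residence time), runs the matched
#' protected-vs-control comparison using the ensemble metrics as outcomes,
#' aggregates species exposure, and writes a deterministic artifact
#' directory. Identical `config` (including seed) gives byte-identical
#' text outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; contents overwritten).
#' @return Invisibly, a list of the in-memory stage results (`fields`,
#'   `ensembles`, `overlay`, `pa_table`, `match`, `species`, `coverage`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("metrics", "ensemble", "overlay", "tables"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  # manifest hash: md5 of the canonical config serialization
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- file.path(out_dir, "manifest.json")
  manifest <- list(package = "climrisk",
                   version = as.character(utils::packageVersion("climrisk")),
                   seed = cfg$seed, config = unclass(cfg))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), tf)
  hash <- unname(tools::md5sum(tf))

  grid <- grid_spec(cfg$n_rows, cfg$n_cols, cfg$cell_size_km)
  vars <- c("temperature", "precipitation")

  t0 <- proc.time()["elapsed"]
  stage_log(cfg, "simulate: %d x %d grid, %d members", cfg$n_rows, cfg$n_cols,
            length(cfg$esm_trends))
  base_series <- list()
  for (v in vars) {
    p <- cfg[[v]]
    base_series[[v]] <- make_planar_series(
      grid, cfg$years_baseline, variable = v, base_value = p$base,
      spatial_gradient = p$gradient, temporal_trend = p$trend,
      noise_sd = p$noise_sd, gradient_axis = p$axis,
      seed = cfg$seed + 11 + match(v, vars))
  }
  base_clims <- lapply(base_series, climatology)

  fields <- list()   # fields[[esm]][[metric]]
  esms <- names(cfg$esm_trends)
  for (e in esms) {
    fut_series <- list()
    for (v in vars) {
      p <- cfg[[v]]
      trend_f <- if (v == "temperature") cfg$esm_trends[[e]] else p$trend
      fut_series[[v]] <- make_planar_series(
        grid, cfg$years_future, variable = v, base_value = p$base,
        spatial_gradient = p$gradient, temporal_trend = trend_f,
        noise_sd = p$noise_sd, gradient_axis = p$axis,
        ref_year = cfg$years_baseline[1], period_label = "future",
        seed = cfg$seed + 101 + 7 * match(e, esms) + match(v, vars))
    }
    fut_clims <- lapply(fut_series, climatology)
    vel <- list()
    for (v in vars) {
      tr <- temporal_trend(base_series[[v]], fut_series[[v]])
      gr <- spatial_gradient(base_clims[[v]])
      vel[[v]] <- local_velocity(tr, gr, cfg$gradient_floor,
                                 scenario = cfg$scenario, esm = e)
    }
    fields[[e]] <- list(
      local_velocity = combine_abs_sum(vel$temperature, vel$precipitation),
      analog_velocity = analog_velocity(base_clims, fut_clims,
                                        threshold_sd = cfg$threshold_sd,
                                        radius_km = cfg$radius_km,
                                        elapsed_yr = cfg$elapsed_yr,
                                        scenario = cfg$scenario, esm = e),
      magnitude = magnitude_sed(base_clims, fut_clims,
                                scenario = cfg$scenario, esm = e))
    for (m in names(fields[[e]])) {
      p <- file.path(out_dir, "metrics",
                     sprintf("%s_%s_%s.nc", cfg$scenario, e, m))
      write_field(fields[[e]][[m]], p)
    }
  }
  stage_log(cfg, "metrics done (%.1f s)", proc.time()["elapsed"] - t0)

  ensembles <- list()
  for (m in c("local_velocity", "analog_velocity", "magnitude")) {
    ensembles[[m]] <- ensemble_fields(lapply(fields, `[[`, m))
    ef <- exposure_field(ensembles[[m]]$mean_grid, m, grid,
                         scenario = cfg$scenario, esm = "ensemble_mean")
    write_field(ef, file.path(out_dir, "ensemble",
                              sprintf("%s_%s_mean.nc", cfg$scenario, m)))
  }

  masks <- list(local = quartile_masks(ensembles$local_velocity),
                analog = quartile_masks(ensembles$analog_velocity),
                magnitude = quartile_masks(ensembles$magnitude))
  no_analog_any <- Reduce(`|`, lapply(fields, function(f)
    f$analog_velocity$no_analog_mask))
  overlay <- overlay_code(masks, no_analog = no_analog_any, grid = grid)
  ocode <- overlay$code_grid
  write_asc(ocode, grid, file.path(out_dir, "overlay",
                                   sprintf("overlay_%s.asc", cfg$scenario)))
  write_csv_manifest(overlay$code_table,
                     file.path(out_dir, "overlay", "code_table.csv"), hash)

  stage_log(cfg, "landscape + zonal")
  land <- make_protected_landscape(
    grid, n_polygons = cfg$n_polygons, area_range = cfg$area_range,
    marginal_frac = cfg$marginal_frac, n_regions = cfg$n_regions,
    seed = cfg$seed + 541)
  write_pa_geojson(land$pas, file.path(out_dir, "polygons.geojson"))

  pa_table <- NULL
  species <- NULL
  if (cfg$n_polygons > 0) {
    pa_table <- pa_exposure_table(
      land$pas,
      list(local_velocity = ensembles$local_velocity,
           analog_velocity = ensembles$analog_velocity,
           magnitude = ensembles$magnitude),
      velocity_field = ensembles$local_velocity,
      velocity_floor = cfg$velocity_floor)
    write_csv_manifest(pa_table,
                       file.path(out_dir, "tables", "pa_exposure.csv"), hash)

    occ <- make_species_occurrences(cfg$n_species, pa_table$polygon_id,
                                    occupancy_prob = cfg$occupancy_prob,
                                    range_overlap = TRUE,
                                    seed = cfg$seed + 733)
    site_values <- data.frame(site_id = pa_table$polygon_id,
                              local_velocity = pa_table$median_local_velocity,
                              analog_velocity = pa_table$median_analog_velocity,
                              magnitude = pa_table$median_magnitude,
                              stringsAsFactors = FALSE)
    areas <- stats::setNames(pa_table$area_km2, pa_table$polygon_id)
    species <- species_exposure(occ, site_values, site_areas = areas)
    write_csv_manifest(species,
                       file.path(out_dir, "tables", "species_exposure.csv"), hash)
  }

  coverage <- pa_coverage(overlay, land$protection_fraction, pas = land$pas,
                          grid = grid)
  write_csv_manifest(coverage$cells,
                     file.path(out_dir, "tables", "coverage_cells.csv"), hash)
  if (!is.null(coverage$polygons))
    write_csv_manifest(coverage$polygons,
                       file.path(out_dir, "tables", "coverage_polygons.csv"), hash)

  stage_log(cfg, "matching")
  cells <- land$cells
  for (m in names(ensembles)) cells[[m]] <- as.vector(ensembles[[m]]$mean_grid)
  cov_names <- setdiff(names(default_protection_model()), "intercept")
  match <- match_report(cells, cov_names,
                        outcome_names = names(ensembles),
                        caliper_sd = cfg$caliper_sd)
  write_csv_manifest(match$pairs, file.path(out_dir, "tables", "pairs.csv"), hash)
  write_csv_manifest(match$balance, file.path(out_dir, "tables", "balance.csv"), hash)
  write_csv_manifest(match$c_statistic,
                     file.path(out_dir, "tables", "c_statistic.csv"), hash)
  write_csv_manifest(match$wilcoxon,
                     file.path(out_dir, "tables", "wilcoxon.csv"), hash)
  stage_log(cfg, "done (%.1f s total)", proc.time()["elapsed"] - t0)

  invisible(list(fields = fields, ensembles = ensembles, overlay = overlay,
                 pa_table = pa_table, match = match, species = species,
                 coverage = coverage, landscape = land,
                 manifest = manifest, manifest_hash = hash))
}
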