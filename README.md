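# climrisk

Multi-metric climate-change exposure analysis for protected-area networks.

`climrisk` quantifies how fast, how far, and how profoundly climate
conditions are projected to change across a landscape, and what that
implies for protected areas (PAs) and the species they host. It is aimed at
spatial ecologists and conservation planners working with gridded yearly
climate projections on an equal-area grid (e.g. 1 km ETRS89-LAEA over
Europe) and PA polygon sets (e.g. dissolved WDPA/Natura 2000 polygons).

## The four exposure metrics

For each climate variable *k* (mean annual temperature, annual
precipitation), cell *i*, baseline climatology mean *a_ki*, future
climatology mean *b_ki*, and baseline interannual SD *s_ki*:

* **Local (gradient-based) climate velocity** — the speed at which an
  isopleth of a variable moves across the landscape:

  `v_local = slope / |∇s|`  (km/yr)

  with `slope` the per-cell OLS trend (units/yr) over the concatenated
  baseline + future yearly series and `|∇s|` the local spatial gradient
  (units/km) from a 3×3-cell neighborhood. Per-variable velocities are
  signed; maps combine them as `|v_temp| + |v_prec|`.

* **Analog (distance-based) climate velocity** — how far a species must
  move to track its current climate:

  `v_analog = d / t`  (km/yr)

  where `d` is the distance to the geographically closest cell whose
  *future* climate lies within 1.5 standardized units
  (`‖(b_kj − a_ki)/s_ki‖ ≤ 1.5`) of the focal cell's current climate,
  searched within a 1500 km radius, and `t` is the elapsed time between
  climatology midpoints (60 yr). Cells with no analog are flagged.

* **Magnitude** — the standardized Euclidean distance (SED) between
  baseline and future climate at a fixed location:

  `SED_i = sqrt( Σ_k (b_ki − a_ki)² / s_ki² )`

* **Residence time** — years until current conditions leave a PA polygon:

  `RT = d_i / gV_i ≈ 2·sqrt(A_i/π) / gV_i`

  with `A_i` the polygon area and `gV_i` its mean local velocity.

Around these, the package provides multi-model ensemble summaries
(mean/SD across ESM members), quartile **hotspot/coldspot** classification
with a multi-metric overlay, **propensity-score matching** of protected vs.
control cells (logistic scores, nearest-neighbor matching without
replacement, 0.25 SD caliper, SMD and C-statistic balance diagnostics,
paired Wilcoxon tests per biogeographic region), and **species-level
exposure** aggregation over occupied sites (median and area-weighted).
Seeded synthetic generators produce planar climates, confounded protected
landscapes and species occurrences with analytically known ground truth.

## Worked example

```r
library(climrisk)

# a planar temperature field warming 0.05 degC/yr over a 0.01 degC/km
# west-east gradient: every isotherm moves 5 km/yr eastward
g  <- grid_spec(100, 100, cell_size = 10)          # 1000 x 1000 km
b  <- make_planar_series(g, 1981:2010, temporal_trend = 0.05,
                         spatial_gradient = 0.01, noise_sd = 0)
f  <- make_planar_series(g, 2041:2070, temporal_trend = 0.05,
                         spatial_gradient = 0.01, noise_sd = 0,
                         ref_year = 1981, period_label = "future")
v  <- local_velocity(temporal_trend(b, f), spatial_gradient(climatology(b)))
print(v)
#> <exposure_field> local_velocity [unspecified/unspecified], grid 100x100 @ 10 km
#>   valid cells: 10000/10000; median 5; range [5, 5]

# residence time of a 10 km radius disc on a uniform 2 km/yr landscape
g2 <- grid_spec(30, 30, 2)
b2 <- make_planar_series(g2, 1981:2010, temporal_trend = 0.02,
                         spatial_gradient = 0.01, noise_sd = 0)
f2 <- make_planar_series(g2, 2041:2070, temporal_trend = 0.02,
                         spatial_gradient = 0.01, noise_sd = 0,
                         ref_year = 1981, period_label = "future")
v2 <- local_velocity(temporal_trend(b2, f2), spatial_gradient(climatology(b2)))
pas <- pa_set(list(climrisk:::geom_disc(c(30, -30), 10)), "disc")
pa_exposure_table(pas, list(local_velocity = v2))[,
  c("polygon_id", "area_km2", "diameter_km", "residence_time_yr")]
#>   polygon_id area_km2 diameter_km residence_time_yr
#> 1       disc 314.1593          20                10
```

A disc of area `π·10²` km² has equivalent diameter 20 km; at 2 km/yr its
climate residence time is 10 years — the pipeline recovers this to within
rasterization error.

The full end-to-end analysis (synthetic inputs → metrics → ensembles →
overlay → polygon tables → matching → species tables) is one call:

```r
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, "out/")
print(res$match)
#> <match_report> 535 pairs (555 treated, 1505 control cells; 20 discarded)
#>   C-statistic before 0.720 -> after (refit) 0.524; max SMD after 0.108
```

Identical configurations produce byte-identical text outputs. A thin CLI
wrapper with `simulate` and `run` subcommands is installed at
`inst/cli/climrisk.R`.

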