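# radarcvp

Estimating aerial arthropod abundance from dual-polarization weather
surveillance radar.

Operational weather radars record, besides rain, the "clear-air" echo of
insects and other arthropods flying at 100–2100 m. `radarcvp` turns polar
radar volumes of reflectivity factor (Z, dBZ), differential reflectivity
(Z_DR, dB) and co-polar correlation (rho_HV) into per-column, per-height-band
arthropod densities and long-term trends, for ecologists and radar
aeroecologists who want standardized abundance monitoring from meteorological
infrastructure.

The workflow:

* **Columnar vertical profiles (CVPs)** — a 12 × 12 lattice of 2.5 km-radius
  columns on 5 km spacing around each radar (144 columns; 16 central and 1
  corner column removed, 127 retained; terrain-blocked columns masked by a
  beam-axis rule), each cut into ten 200 m bands between 100 and 2100 m.
  Gates are azimuthally averaged per (column, band), reflectivity in linear
  units.
* **Echo filtering** — precipitation removed by the depolarization ratio
  DR = 10 log10[(ζ + 1 − 2√ζρ)/(ζ + 1 + 2√ζρ)], ζ = 10^(Z_DR/10), at
  DR < −12.5 dB; extreme returns removed at Z > 45 dBZ; birds removed by
  retaining only Z_DR > 3 dB.
* **Abundance conversion** — η(dB) = Z + β with the Rayleigh offset
  β = 10 log10(10³ π⁵ |K_m|²/λ⁴) = 26.58 dB for the C-band network; number
  density = η_lin/σ, with σ the mean single-arthropod radar cross-section
  (cm², supplied explicitly — it has no default).
* **Activity windows** — cyclic-spline fits to Z_DR time series identify the
  high-activity season and the two diel peaks; one scan (max Z_DR) per
  window per column per day enters the analysis. Operational presets:
  08–14 h and 18–22 h GMT, 15 April–30 October.
* **Validation and trends** — standardized OLS against ground suction-trap
  counts (slope = Pearson r, rain days excluded), and hierarchical
  spatio-temporal GAMs (`mgcv::bam`, double-penalty selection, AR(1) errors,
  Moran's I residual correlograms, prediction surfaces with delta-method
  SEs, annual trends and change maps).
* **Synthetic scenes** — a generator that paints insect layers, rain cells,
  bird echoes and clear-air background into full polar volumes with exact
  ground truth, so the whole pipeline is verifiable.

## Worked example

Simulate one July day over a compact scan geometry, filter it, select one
scan per diel window, and convert to abundance:

```r
library(radarcvp)

site    <- radar_site(site_id = "demo", azimuth_step = 3,
                      elevation_angles = seq(0.5, 4, by = 1), max_range = 45)
lattice <- build_cvp_lattice(site)
lattice
#> CVP lattice for site <demo>: 144 cells
#>    central_clutter corner_unprocessed           retained
#>                 16                  1                127

mapping <- assign_gates_to_columns(lattice, site)
study   <- simulate_study(scene_config(seed = 1), site, lattice,
                          as.Date("2021-07-01"), hours = c(8, 22),
                          scan_interval_min = 60, mapping = mapping)
study
#> Synthetic study archive: 10864 raw and 8426 filtered profile rows
#>   gate labels:
#>     missing precipitation high_reflectivity arthropod bird_like
#>           0         48747                 0    311278    143975

sel    <- select_scan_per_window(study$profiles_raw, preset_windows()$diel,
                                 band = 500)
consts <- radar_constants(sigma = 1)   # cm^2; always supplied explicitly
est    <- abundance_estimates(study$profiles_filtered, sel, consts)

b500 <- est[est$band_lower == 500, ]
median(b500$density[b500$window == "diurnal"])    # 3157 per km^3
median(b500$density[b500$window == "nocturnal"])  # 3032 per km^3
```

The diurnal median (3157 km⁻³) sits close to the scene's painted truth at
the 500 m band (4100 km⁻³ at the 11:00 activity peak, less at the selected
scans' actual activity), and exceeds the nocturnal median, as the simulated
diel curve (amplitudes 1 vs 0.8) prescribes. Derived summaries follow the
same pattern:

```r
diurnal <- est[est$window == "diurnal", ]
vertical_gradient(diurnal$band_lower, diurnal$total_count)$slope
#> -1372   # individuals per 200 m of height gained (adj R^2 0.76)

extrapolate_region(median(b500$density[b500$window == "diurnal"]),
                   region_area_km2 = 35728, band_depth_km = 0.2)
#> 2.256e+07   # individuals aloft over a 35,728 km^2 region in one band
```

The negative vertical gradient recovers the scene's height-declining insect
layer; the extrapolation is the density × area × depth product with both
the regional mean and the reference area as explicit inputs.

`run_end_to_end(run_config(...))` chains all stages (geometry →
classification → profiles → windows → abundance → optional trend model) and
writes CSV artifacts plus a JSON manifest with every threshold, seed and
file checksum; `inst/scripts/radarcvp-cli.R` wraps it for shell use.

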