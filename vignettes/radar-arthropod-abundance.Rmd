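---
title: "Estimating aerial arthropod abundance from dual-polarization weather radar"
author: "radarcvp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating aerial arthropod abundance from dual-polarization weather radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarcvp)
```

## The problem

Operational weather-surveillance radars observe the airspace continuously,
and a large fraction of their "clear-air" echo is biological: insects and
other arthropods drifting or flying at heights of a few hundred metres to a
couple of kilometres. With dual polarization, three gate-level moments are
available — reflectivity factor $Z$ (dBZ), differential reflectivity
$Z_{DR}$ (dB), and the co-polar correlation coefficient $\rho_{HV}$ — and
these suffice to (i) separate bioscatter from precipitation, (ii) separate
elongated arthropods from birds, and (iii) convert the retained reflectivity
into a number density of animals per unit air volume. `radarcvp` implements
that workflow end to end, together with the spatio-temporal trend models
used to interpret the resulting abundance series, and a synthetic scene
generator with exact ground truth to verify every step.

## Columnar vertical profiles

Around each radar we build a $12 \times 12$ lattice of columnar vertical
profiles (CVPs): cylinders of radius 2.5 km on 5 km spacing, covering a
$60 \times 60$ km box (144 columns). Beyond ~30 km radar sensitivity to
small targets degrades, which motivates the box size. Each column is cut
into ten 200 m height bands spanning 100–2100 m above the radar ground
reference (bands are addressed by their lower edge and are half-open, so a
gate at exactly 2100 m belongs to no band).

Sixteen central columns (the $4\times4$ block within 7.5 km) are discarded
because the highest bands are unobservable so close to the radar, and one
corner column is conventionally unprocessed, leaving 127 usable columns per
radar. Columns whose lowest beam intersects terrain are additionally masked
(`terrain_mask()`): the beam axis at the lowest elevation is marched from
the radar to the column centre at gate-length resolution and the column is
dropped if terrain reaches the axis. This beam-axis rule is deliberately
simple and auditable; it does not model partial beam blockage, and it will
not reproduce any particular operational blockage census on other terrain.

Gate positions use the standard 4/3-effective-earth-radius beam propagation
(Earth radius 6371 km) and a flat ground projection $g = r\cos\theta$,
whose error at 30 km is below 0.1%. Heights are above the radar ground
reference, matching the band definitions. Each gate maps to the retained
column whose centre lies within 2.5 km; because tangent circles on a 5 km
grid overlap only on a measure-zero boundary, assignment is effectively
unique (exact ties go to the nearest centre, then lowest row/column).

Within a (column, band, scan) cell, reflectivity is averaged in *linear*
units (reflectivity is power-additive; averaging in dB would
underestimate), $Z_{DR}$ in dB and $\rho_{HV}$ in natural units. Bands with
fewer than `min_gates = 3` surviving gates are marked invalid rather than
zero: absence of signal is instrumental, not biological. Single-gate bands
are noise-prone, hence the default of 3; set `min_gates = 1` for the most
literal reading of the averaging rule.

## Echo classification

The per-gate filter applies, in order:

1. **Precipitation.** The depolarization ratio
   $DR = 10\log_{10}\frac{\zeta + 1 - 2\sqrt{\zeta}\rho}{\zeta + 1 +
   2\sqrt{\zeta}\rho}$, $\zeta = 10^{Z_{DR}/10}$, is very negative for
   near-spherical, well-correlated raindrops and near zero for irregular
   biological targets. Gates with $DR < -12.5$ dB are removed. When the
   ratio underflows ($\rho \to 1$ at $\zeta = 1$) DR is floored at −60 dB,
   far below any threshold in use.
2. **Extreme reflectivity.** Gates with $Z > 45$ dBZ (hail, heavy rain that
   can evade the DR rule) are removed.
3. **Birds.** Of the remainder, gates are retained as arthropods only when
   $Z_{DR} > 3$ dB — elongated fliers commonly show 2–10 dB, birds cluster
   lower. 3 dB is conservative for a mixed fauna; strongly elongated taxa
   (mayflies) support 5 dB. The inequalities are strict in the directions
   stated ("below −12.5", "above 45", "above 3"), so boundary gates are
   kept by the first two rules and excluded by the third.

A gate failing an earlier test never reaches a later one; every gate gets
exactly one of five labels (missing, precipitation, high-reflectivity,
arthropod, bird-like) and label counts always sum to the gate total. All
thresholds are configurable per run and echoed into output metadata.

## Activity windows and scan selection

Arthropod activity is strongly structured in time: a season running from
mid-spring to mid-autumn and, within a day, a midday peak and a dusk peak.
The observable signature is the *all-echo* mean $Z_{DR}$ of a band: when
arthropods are airborne, the echo mixture shifts towards their high
$Z_{DR}$; when they are absent, the weak clear-air background dominates near
0 dB. (The arthropod-only mean $Z_{DR}$ is nearly constant by construction
and carries no activity signal, which is why `activity_series()` pools
profiles built from raw, unfiltered volumes.)

`fit_activity_smooth()` fits a penalized *cyclic* spline (period 24 h or
366 d; basis dimension 10/20, smoothness by GCV) to that series and reports
the local maxima of the fitted curve. `extract_peak_windows()` turns the
curve into windows: the contiguous regions, one per local maximum, where the
fit stays at or above 50% of its peak height above baseline, rounded outward
to whole hours/days. The 50% rule is this package's own operational
definition — published workflows typically state the resulting windows, not
the extraction criterion — and the conventional fixed windows
(08–14 h and 18–22 h GMT; 15 April–30 October, days 105–303) are available
as `preset_windows()` so the pipeline can bypass fitting entirely. The
fixed GMT windows deliberately ignore latitude-dependent twilight; the dusk
window may include civil twilight.

Within each window of each day, exactly one scan per column is used for
abundance — the scan with maximal band $Z_{DR}$ (ties broken by the earliest
timestamp). Selecting a single scan avoids double-counting individuals that
make repeated flights or remain airborne across successive scans, and makes
the unequal window lengths (6 h vs 4 h) comparable. Selection is per column,
because estimates are per column; it is invariant to monotone transforms of
$Z_{DR}$.

## From reflectivity to abundance

Band mean reflectivity factor converts to reflectivity $\eta$ (cm² km⁻³)
through the Rayleigh offset:
$$\eta_{dB} = Z + \beta, \qquad
  \beta = 10\log_{10}\!\left(10^{3}\pi^{5}|K_m|^{2}/\lambda^{4}\right),$$
with $\lambda$ in cm and $|K_m|^2 = 0.93$. The operational C-band constant
is $\beta = 26.58$ dB, which this formula reproduces at $\lambda = 5.0$ cm;
note that C-band magnetrons are often quoted at 5.3 cm, for which the
formula gives 25.57 dB. `radarcvp` treats the printed operational constant
as authoritative while exposing both routes (`radar_constants()` accepts
`beta` directly or computes it from `wavelength`) and logs which was used.

Linear $\eta$ times the band volume $V_h = \pi r^2 h$ ($r = 2.5$ km,
$h = 0.2$ km, $V_h \approx 3.93$ km³) gives the total backscattering area,
and dividing by the mean radar cross-section $\sigma$ (cm²) of a single
arthropod gives a head count; density is count$/V_h = \eta_{lin}/\sigma$,
independent of $V_h$. $\sigma$ **has no default**: it is a study-specific
calibration (it depends on the size mix of the local fauna), so the package
refuses to run without an explicit value rather than silently assuming one.
The synthetic generator's `sigma_true` plays that role in tests.

Derived summaries: `vertical_gradient()` (OLS slope of abundance on band
index with SE, adjusted R² and p), `extrapolate_region()` (density × area ×
band depth, with both the regional mean and reference area as explicit
inputs), and `trap_validation_ols()`, which z-scores daily trap counts and
radar estimates before regression — so the slope *is* the Pearson
correlation — and excludes flagged heavy-rain days.

## Trend modelling

Abundance densities (log10(x+1)-transformed by default — the response is
continuous reflectivity-derived density, fitted with Gaussian errors, and
spans orders of magnitude) are modelled with hierarchical additive models:
thin-plate spline smooths of climate and land-cover covariates, a spatial
smooth $f(x, y)$ of column centroids, a year smooth, optional year-by-radar
smooths and random intercepts for radar, month and grid cell. Fitting uses
`mgcv::bam` with fast REML and the double-penalty shrinkage
(`select = TRUE`), which can remove an uninformative covariate entirely.
Temporal autocorrelation uses an AR(1) error model: a first pass without
correlation supplies residuals to `estimate_rho()` (pooled within-series
lag-1 autocorrelation), and the model is refitted at that rho via `bam`'s
`rho`/`AR.start` mechanism. Basis dimensions default to $k = 8$ for 1-D
smooths and $k = 30$ for $f(x,y)$ — modest values chosen a priori; k-index
diagnostics remain available through `mgcv::gam.check`.

`candidate_ladder()` provides seven nested candidates (year smooth → +
spatial → + random intercepts → + climate → + land cover → full → + year-by-
radar); `select_best_model()` fits all and ranks by AIC with ΔAIC, adjusted
R² and deviance explained, recording failures instead of crashing.

Residual spatial structure is diagnosed with `morans_i_correlogram()`:
Moran's I in binary distance bands with expectation $-1/(n-1)$ and a
permutation p-value per band (p-values across bands are reported
unadjusted). One numerical subtlety matters: residuals of a model that
*contains* a spatial smooth are slightly negatively autocorrelated at short
range, because the smooth absorbs part of each neighbourhood's mean. A
two-sided test therefore flags correctly specified models. The package's
residual-cleanliness checks use `alternative = "greater"` — the diagnostic
question is whether unmodelled *positive* clustering remains — while the
two-sided test stays the default for general correlograms.

`predict_map()` evaluates the fitted linear predictor over covariate raster
stacks per year, with delta-method standard errors from the coefficient
covariance, random intercepts at population level, and per-pixel flags when
a covariate leaves its training range. `annual_trend()` averages predictions
over columns per year (SEs propagated through the averaged linear
predictor) and differences the last and first year per column — on the
log10 scale when the response was transformed — giving the change map.

## The synthetic scene and what it does (not) show

`scene_config()` defines a generative model painted into full polar
volumes:

* **Insects** occupy 100–2100 m with density declining linearly with band
  (default 5000 km⁻³ at the lowest band, −450 km⁻³ per band step), modulated
  by a two-Gaussian diel curve (peaks 11:00 and 20:00 GMT, widths 1.5/1.2 h,
  amplitudes 1/0.8) and a seasonal Gaussian envelope (peak day 200, SD 38 d,
  hard zero outside days 60–334). The widths and SD were fixed at design
  time so that the *observable* Z_DR series shows two clearly separated
  diel peaks and a Z_DR-visible season of roughly late April–mid October,
  the phenology the scene is meant to emulate. Gate reflectivity follows the
  forward model $Z = 10\log_{10}(d\,\sigma_{true}) - \beta$; $Z_{DR}$ is
  truncated-normal above 3 dB (mean 6, SD 1.5) and $\rho_{HV}$ uniform on
  [0.3, 0.7], so DR stays far above −12.5 dB.
* **Precipitation cells** are discs with $Z \sim U(20, 55)$ dBZ,
  $Z_{DR} \approx 0.8$ dB, $\rho_{HV} \approx 0.99$ (DR ≈ −21 dB).
* **Bird-like gates** sit at $Z_{DR} \sim N(2, 0.3)$ dB so the 3 dB cut
  removes most but not all — threshold behaviour, not perfect separation,
  is what gets tested.
* **Clear-air background** (−5 dBZ, $Z_{DR} \approx 0.5$ dB) mixes with the
  insect return in linear power ($Z_{DR}$ and $\rho_{HV}$ combine
  power-weighted), which is what makes the all-echo mean $Z_{DR}$ track
  activity smoothly.

Measurement noise is added in instrument units (dBZ, dB, unitless with
$\rho_{HV}$ truncated to [0, 1]); gates below −20 dBZ are missing. Every
generator derives its RNG stream from the config seed plus the scan
timestamp, so identical configs are bit-identical regardless of call order.

With noise off, background off and constant activity, the pipeline recovers
the painted density to machine precision in every valid band of every
column — the forward model and the inversion are exact inverses, and the
test suite asserts this at 10⁻⁶ relative tolerance. What passing these
tests does *not* show: the scene has no storm morphology, no Mie/T-matrix
scattering, no bird migration dynamics, no correlated instrument drift, and
its background is spatially homogeneous. Agreement on the synthetic scene
verifies the algebra and the plumbing, not the biological fidelity of any
particular $\sigma$ or threshold on real data.

Covariate rasters are Gaussian-filtered white noise scaled to realistic
ranges (Tmax 12–24 °C, ALAN 0–63 DN, land-cover percentages summing to
≤ 100 via a 5-class softmax), with user-supplied effect functions carried
through as truth. `simulate_trend_table()` builds the trend-model test bed
directly: known smooth effects (covariates drawn independently per row so
recovery is unconfounded), a spatial surface, a north–south sign-flipping
year trend, and AR(1) noise per column. `simulate_validation_series()`
generates the trap/radar pair with band loadings on a shared daily signal
decreasing linearly from 0.9 to 0.1 with height — chosen a priori so
adjacent-band correlation gaps (~0.1) exceed sampling noise at the series
lengths used in tests.

## Problem sizes and numerical choices

The verification runs use a compact but complete scan geometry (45 km
range, 3–6° azimuth sectors, 4 elevations) so that full volumes remain
cheap: a simulated day of 48 volumes takes a few seconds. The trend
recovery test bed uses 127 columns × 8 years × 2 observations (n = 2032)
with AR(1) rho 0.6 and innovation SD 0.3; diel window recovery uses 20
seeded one-day replicates at 30-min scans; model-selection ranking is
exercised with 5 replicate tables over a 3-candidate ladder; the
trap-validation monotonicity check uses 2000-day series. Ties in scan
selection go to the earliest timestamp; exact gate-assignment ties to the
lowest (row, col); rho estimates are clamped to [0, 0.98] before refitting;
intercept-only candidates fit as plain parametric models (shrinkage
selection needs at least one smooth).

## Known limitations

* The beam-axis terrain rule ignores partial blockage and anomalous
  propagation.
* No range-dependent weighting inside a column; all gates in a band count
  equally.
* $\sigma$ is a single scalar: no taxon or size decomposition, and no
  orientation dependence of $Z_{DR}$.
* The AR(1) model is per column with a single pooled rho; cross-column
  error correlation beyond $f(x,y)$ is not modelled.
* Windows are network-global, not per site; latitude-dependent twilight is
  deliberately ignored.
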