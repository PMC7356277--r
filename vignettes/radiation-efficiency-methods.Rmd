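---
title: "Radiation-efficiency methods: models, defaults and rationale"
output: rmarkdown::html_document
---

This vignette documents the models implemented in `potatoRUE`, the default
parameter values and why they were chosen, what the synthetic trial generator
does and does not emulate, and the numerical choices behind the fitting
routines. It is shipped as source and is not built during installation.

## 1. Thermal time

All phenology runs on accumulated thermal time

$$ tt(d) = \sum_{k=1}^{d} \max\!\left(0,\ \frac{T_{min,k} + T_{max,k}}{2} - T_{base}\right), $$

with `t_base = 2` °C, an established base temperature for potato canopy
development in cool environments. `thermal_time()` returns daily increments
and the cumulative series indexed by day after planting (dap), where dap 1 is
the day following planting.

## 2. Canopy cover: Beta determinate-growth curve

Canopy cover — the proxy for the intercepted-radiation fraction $f$ — follows
the Beta determinate-growth curve of thermal time $t$:

$$ cc(t) = cc_{max}\left(1 + \frac{t_e - t}{t_e - t_m}\right)
           \left(\frac{t}{t_e}\right)^{t_e/(t_e - t_m)}, \qquad t \le t_e, $$

which rises from 0, has its inflection at $t_m$ and peaks at $cc_{max}$ when
$t = t_e$. Beyond $t_e$ the model continues with a linear senescence decline
`cc_max + decline_slope * (t - te)`, clipped to $[0, 1]$.

**Fitting.** `fit_beta_canopy()` fits all four parameters
$(cc_{max}, t_m/t_e, t_e, slope)$ jointly by least squares on the full
piecewise curve, rather than the common two-stage practice of fitting the
rise and the decline separately. Joint fitting uses every flight to constrain
$t_e$, which a two-stage split would have to fix from the empirical maximum;
with only 13 weekly flights this noticeably stabilizes the peak estimate.
The optimizer is bounded Nelder–Mead with an L-BFGS-B polish from three
deterministic starts (the empirical estimate plus two fixed multiplicative
perturbations), so the fit is fully reproducible. $t_m$ is parameterized as
a fraction of $t_e$ to keep the constraint $0 < t_m < t_e$ box-shaped.
The fit requires at least 5 flights with at least one after the empirical
maximum; otherwise the decline is unidentifiable and an error is raised.

## 3. Interception, growth and partitioning

Daily interception uses $f(t) = cc(t)$; seasonal quantities are

$$ PAR_{int} = \sum_d f(t_d)\, PAR_{inc,d}, \qquad
   \varepsilon_i = 100\, PAR_{int} / PAR_{inc}. $$

Total dry biomass accumulates as $RUE \cdot f(t_d) \cdot PAR_{inc,d}$
(g m$^{-2}$), converted to per-plant mass by the ground area per plant
(default `plant_area = 0.78` m², the trial's planting density). Tuber mass is
running biomass times the Gompertz partition fraction

$$ p(tt) = a_{max} \exp(-\exp(-b\,(tt - t_u))), $$

whose inflection $t_u$ (thermal time of maximum partition rate) is the
tuberization-precocity proxy. Harvest index is tuber over total biomass at
harvest, $\varepsilon_p = 100\,HI$, and
$\varepsilon_c = 100\,RUE / 57.14$ with 57.14 g MJ$^{-1}$ following from an
assumed biomass energy content of 17.5 MJ kg$^{-1}$. Cross-crop relative
efficiencies divide by theoretical maxima: $\varepsilon_i$ 90% for all
crops, $\varepsilon_c$ 9.4% (C3) / 12.3% (C4), $\varepsilon_p$ 65% for
grain/seed crops and 90% for storage-organ crops.

## 4. Calibration

`calibrate_growth()` minimizes the mean relative error
$\frac{1}{n}\sum |sim - obs| / obs$ between observed and simulated tuber dry
mass. Two numerical choices matter:

- **`a_max` is fixed by default.** Simulated tuber mass depends on RUE and
  $a_{max}$ only through their product near the asymptote, so the pair is not
  identifiable from tuber mass alone. The asymptote must come from outside
  the calibration (here: the accession's configured value; in a real trial,
  from destructive biomass sampling).
- **Deterministic grid-seeded multi-start.** The objective has a distinct
  local basin at high $b$ (a step-like partition curve can fit a handful of
  observation points well while misplacing $t_u$ badly). A coarse
  deterministic grid over $(b, t_u)$ — 12 log-spaced $b$ values × 15 linear
  $t_u$ values, with RUE profiled out as the clamped median observed/modeled
  ratio — seeds bounded Nelder–Mead starts (plus the user start and one
  seeded random draw), each polished with L-BFGS-B. On noiseless trials this
  recovers RUE within 0.02% and $t_u$ within 0.7%.

## 5. Imaging defaults

- **Endmember spectra**: vegetation (green 0.10, red 0.08, NIR 0.50), soil
  (0.18, 0.20, 0.25), giving NDVI ≈ 0.72 over full canopy and ≈ 0.11 over
  bare soil — cleanly separable classes typical of calibrated reflectance
  products.
- **SAVI threshold 0.3** with `L = 0.5`: the two endmembers score SAVI
  ≈ 0.58 and ≈ 0.08, so 0.3 sits mid-gap and is robust to per-pixel noise of
  SD 0.01 reflectance units. An Otsu automatic threshold is available for
  scenes where the fixed value is unsuitable.
- **NDVI senescence slope**: ordinary least-squares slope of plot-mean NDVI
  on dap from the flight of maximum NDVI to the last flight (≥ 3 flights);
  values closer to zero indicate a longer senescence delay.

## 6. What the synthetic generator emulates

The generator reproduces the study *conditions*, not the study data:

- **Weather**: daily values drawn around the Lima winter monthly means
  (July–November), with daily SD reconstructed from the printed standard
  error of the monthly mean as `SE * sqrt(days in month)`; PAR truncated at
  0 and `tmin <= tmax` enforced. `dispersion = 0` returns the monthly means
  exactly, which reconstructs seasonal cumulative incident PAR of ≈ 570
  (121 dap) and ≈ 700 MJ m$^{-2}$ (141 dap) from a 5 July planting.
- **Design**: 20 unreplicated test accessions augmented by 4 checks in 4
  equal blocks; harvests staggered at 121 or 141 dap.
- **Ground truth**: per-accession parameters uniform within ranges anchored
  to diverse potato germplasm (RUE 1.0–3.6 g MJ$^{-1}$, $t_u$ 356–556
  degree-days, $a_{max}$ 0.63–0.93, peak cover 0.35–0.95). A shared latent
  factor (weight `link = 0.5`) couples high RUE with shallower senescence
  decline and earlier tuberization, emulating the field association between
  senescence delay, earliness and yield.
- **Imagery**: per-flight 64×64 rasters in which `round(cc * 4096)` pixels
  carry the vegetation spectrum, with truncated Gaussian reflectance noise
  (SD 0.01); plot series are then extracted with the same imaging code used
  for real data.
- **Observation noise**: harvest tuber mass gets mean-preserving
  multiplicative lognormal noise (default CV 10%); four observation days per
  plot at 50/65/80/100% of the harvest day. Replicate plots of a check get
  lognormal jitter (SD 0.04) on peak cover and decline slope
  (stand-establishment variability), and plot-level noise on the two
  physiology traits carried as inputs (net photosynthesis `a`, leaf carbon
  isotope discrimination `delta_leaf`).

Not emulated: within-field spatial autocorrelation, weather autocorrelation
between consecutive days, mixed-pixel reflectances at canopy edges, tuber
fresh-to-dry conversion, and any genotype-by-environment structure beyond
the single latent factor.

## 7. Trial statistics

`dau_analysis()` implements the classical augmented-block analysis: block
effects from the replicated checks, test entries adjusted as
`raw - (block check mean - grand check mean)`, a closed-form balanced
checks-by-blocks two-way ANOVA for the error mean square, treatment
partition into checks / augmented / checks-vs-augmented, and Tukey letter
groups using Federer's pair-type variances of a difference
(check–check $2\sigma^2/b$; new–new same block $2\sigma^2$; new–new
different block $2\sigma^2(1 + 1/c)$; check–new
$\sigma^2(1 + 1/b + 1/c + 1/(bc))$). The adjusted means agree with an
independent `lm(y ~ accession + block)` oracle to numerical precision.

PCA is the eigen-decomposition of the trait correlation matrix with a
deterministic sign rule (the largest-magnitude loading on each component is
made positive), cumulative variance reported over the 7 analysis traits
($\varepsilon_i$, $\varepsilon_c$, $\varepsilon_p$, `a`, `delta_leaf`,
NDVI slope, $t_u$). Clustering is Ward (`ward.D2`) on the retained component
scores (default 3), and tuber yield is regressed by OLS on the same
components.

## 8. Problem sizes in the tests

The unit and acceptance tests run reduced trials (6–8 test accessions, 2
checks, 2 blocks) where full size adds runtime but no coverage; the
calibration-quality acceptance check and the reproduction script use the full
default configuration (20 + 4 accessions, 4 blocks, 13 flights, 10% noise),
which completes in well under a minute on one CPU.

## 9. Limitations

- Canopy cover is equated with the intercepted-radiation fraction; no
  extinction-coefficient correction for row geometry or sun angle.
- The calibration returns point estimates only; no uncertainty
  quantification beyond the achieved mean relative error.
- $a_{max}$ must be supplied externally (Section 4); with it misspecified,
  RUE absorbs the error multiplicatively.
- Tukey letter displays use the dominant pair-type variance per comparison;
  with very few checks the check–new comparisons are the limiting ones.
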