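---
title: "Methods: interannual NPP variability analysis for coastal upwelling systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interannual NPP variability analysis for coastal upwelling systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upwellr)
```

## The problem

Eastern-boundary upwelling systems such as the Canary Current off NW
Africa sustain intense phytoplankton productivity because equatorward
winds drive coastal upwelling of cold, nutrient-rich water. In the
southern part of that system (the Senegal–Mauritania coast), net primary
production (NPP) peaks in boreal spring (March–April–May) and its
interannual anomalies swing between extreme low years — co-occurring
with anomalously warm coastal SST ("Dakar Niño" conditions) — and
extreme high years. `upwellr` implements the complete statistical
pipeline used to characterise those extremes from monthly gridded
fields: anomaly construction, threshold-and-duration event detection,
lag composites with a nonparametric bootstrap, a mixed-layer heat-budget
decomposition, climate indices with sliding correlations, and coastal
Hovmöller diagnostics for wave signatures — all exercised end-to-end on
a synthetic-data generator with recorded ground truth.

## Data model

A `gridded_field` holds one variable as a `[time, lat, lon]` array with
coordinate vectors, units and a land/ocean mask; masked cells are `NA`
and excluded from every statistic. The time axis is strictly monthly and
contiguous. Region-mean series are base `ts` objects with frequency 12,
so calendar months resolve through `stats::cycle()`.

Fields serialize to a self-describing JSON text container
(`write_field()`/`read_field()`), with values written at 17 significant
digits so a round trip is the identity. NetCDF would be the natural
interchange format, but no R NetCDF binding is available in the target
environment; the JSON container keeps the same roles (coordinates,
units, fill values, multiple variables per file).

Regions are either latitude–longitude boxes (cell-centre containment,
no partial-cell weighting) or *coastal bands*: per latitude row, ocean
cells within `band_width` degrees of longitude westward of the
westernmost land cell. The paper-defined study region — the coastal
Dakar Niño Index band, 9–18°N with a 2° band — ships in
`region_registry()` together with the Niño3.4, North-Atlantic and
60°S–60°N boxes. The band geometry is a documented interpretation: the
source only says "2°-coastal band", and the NW-African coast is
quasi-meridional in 9–18°N, which makes a longitude offset the simplest
reproducible reading; `region()` lets you configure alternatives.
Area means use cos(latitude) weights — exact for uniform fields
regardless of the weighting, and standard for lat–lon grids.

## Anomaly construction

Anomalies are built pointwise: remove the ordinary-least-squares linear
trend in the month index (slope *and* intercept), then remove the
12-month climatology computed over the whole record.

One numerical subtlety deserves emphasis. At finite monthly sampling a
seasonal cycle is **not** exactly orthogonal to the time index, so
applying the two steps in sequence (either order) leaves a cross-term of
relative order `6·amplitude/n²` in the fitted slope — about `1e-4` on a
21-year record, i.e. harmless for real data but fatal for "output is
exactly zero" identities. `detrended_anomalies()` therefore computes the
*joint* least-squares projection onto {time index, 12 monthly means} —
the fixed point to which iterating the two steps converges. On a pure
trend + cycle input the joint anomalies are zero to machine precision,
a re-fit trend has slope `< 1e-10`, and the output's climatology is zero
for every calendar month. The individual `remove_linear_trend()` and
`deseasonalize()` operations keep their literal sequential semantics,
and the test suite documents the size of the sequential cross-term.

The event threshold uses one pooled standard deviation of the full
detrended, deseasonalized series (all calendar months). The source
study's "±0.8 standard deviation of the interannual NPPA" reads most
naturally as a pooled σ; a per-calendar-month σ can be supplied through
the `sigma` argument of `detect_extreme_events()` instead.

## Extreme events

`detect_extreme_events()` finds maximal runs of consecutive months with
anomaly strictly above `+0.8σ` (high events) or strictly below `-0.8σ`
(low events) lasting at least 2 months. Choices fixed for determinism
and documented in tests: exceedance is strict at the threshold; runs are
never merged across a single sub-threshold month (the literal reading of
"consecutive"); the peak is the month of maximum |anomaly| with ties
broken toward the earlier month; σ is recomputed from the input each
call. `filter_by_peak_season()` keeps events whose *peak* falls in a
season (default MAM) — the start month does not matter.

## Composites and the bootstrap

`composite_at_lags()` averages the anomaly at `peak + lag` across events
for lags −3..+3 months (per cell for maps); events whose lagged month
leaves the record are dropped at that lag with the count tracked.
Significance follows the bootstrap-without-replacement recipe: each of
10,000 artificial composites averages `n_events` *distinct* months drawn
uniformly from the record; a composite value is significant at 95% iff
it falls outside the 2.5th–97.5th percentile range of the sorted
artificial averages. Percentiles use the type-7 (linear interpolation)
convention — a convention must be fixed for bit-reproducibility and the
choice is immaterial at 10,000 resamples. Per-cell tests are
independent, matching per-point 95% masking; there is no
multiple-testing correction. The null pool is the full deseasonalized
record — event months are *not* excluded and all calendar months enter,
matching the literal description of resampling "the initial monthly data
set"; `exclude_months` and `pool_months` expose the stricter variants.
Calibration is verified by Monte-Carlo: on i.i.d. null data the
empirical rejection rate at α = 0.05 is statistically indistinguishable
from 0.05 (acceptance criterion 2).

## Mixed-layer heat budget

The budget terms (`tot`, `xadv`, `yadv`, `zadv`, `ldf`, `zdf`, `qnet`,
all °C day⁻¹) are consumed as given — they are computed online by an
ocean model upstream; this package never differentiates temperature.
`qnet_storage()` implements the flux-storage term
`(Q_ns + Q_sr(1−f)) / (ρ₀ c_p H) × 86400` with ρ₀ = 1027 kg m⁻³ and
c_p = 4000 J kg⁻¹ K⁻¹. `closure_residual()` is `tot` minus the sum of
the six right-hand-side terms — the remainder definition, since whether
the published "residual" is a stored model diagnostic is not stated.

`decompose_qnet()` splits the detrended anomaly of `Q/(ρ₀ c_p H)` into a
flux-anomaly part `δQ/(ρ₀ c_p H̄)` (Q′ term), a mixed-layer-depth part
`δH·Q̄/(ρ₀ c_p H̄²)` (H′ term, entering with a minus sign), and a
residual *defined* as the exact remainder, so
`qnet_ano = q_term − h_term + residual` holds to machine precision for
any input. The overbars are 12-month climatologies (not scalars), and
the δ anomalies use the same joint detrend+deseasonalize pipeline as
every other variable. `contribution_percentages()` implements the
composite accounting rule: the anomalous warming at a lag is the sum of
the positive term anomalies and each positive term contributes
`100·term/total` (cooling symmetric on the negative terms), so reported
percentages always sum to 100.

## Climate indices and correlations

`amv_index()`: monthly North-Atlantic box mean (80°W–0°E, 0–60°N) minus
the 60°S–60°N global band mean, annual means on calendar years, then an
11-year centred running mean leaving 5 missing values at each end.
`nino34_oni()`: Niño3.4 box mean with a 3-month centred running mean and
warm/cold classification at ±0.5 °C. The operational 30-year rolling
base periods are deliberately not implemented — the synthetic pathway
has a single-period climatology and the rolling scheme needs >30 years
of real data.

`sliding_pearson()` computes Pearson r in 21-year centred windows with
the critical value `r* = t*/√(t*² + dof)`. The degrees of freedom
default to `window − 1 = 20` — following the source's explicit statement
("21-year windows yielding 20 degrees of freedom") rather than the
textbook `n − 2` — which reproduces the printed 0.42 threshold at 95%;
pass `dof = window - 2` for the conventional choice.

## Coastal waves

`build_hovmoeller()` band-averages an anomaly field along an ordered
coastal path (1° band by default). Two filters isolate the interannual
wave band, applied in the order highpass-then-smooth: a brick-wall FFT
high-pass and the 1-2-1 running average. The quoted "cut off frequency
of 10 year⁻¹" is dimensionally impossible for monthly data (the Nyquist
frequency is 6 cycles yr⁻¹), so it is read as a cutoff *period* of 10
years (0.1 cycles yr⁻¹); the value is configurable. The zero frequency
is removed, the coefficient exactly at the cutoff period is retained
(passband-inclusive), and hard truncation is used rather than a taper —
the simplest faithful reading of "Fast Fourier Transform filter".
`propagation_lag()` estimates the travel time between two path positions
as the lag maximizing the Pearson cross-correlation, ties broken toward
the smaller |lag|.

## The synthetic world

`generate_fields()` builds every variable as
`climatology(month) + trend·t + AR(1) noise`, with three structural
additions: NPP and SST carry injected multi-month extreme events over
the CDNI band with opposite signs (low productivity co-occurs with warm
SST, the observed anti-phase); sea level anomaly carries a
poleward-propagating coastal Gaussian pulse at a configurable phase
speed; and `generate_budget()` draws six budget terms and consistent
`Q`, `H` series with `tot` set to the exact sum, so closure holds by
construction. Defaults state the world the analysis targets: 21 years
from 2003 on a 1° grid with a meridional coast at 0°E; NPP climatology
peaking in April (the MAM maximum) and SST in September; lag-1
autocorrelation 0.3; and nine MAM-peaking events — six low, three high,
matching the study-period bookkeeping — of 3 months at 3 noise standard
deviations. Events are half-sine pulses so the peak month is
unambiguous; sub-streams per variable are derived from the master seed
at fixed offsets so variables can be regenerated independently; an
optional spatially-correlated noise mode blurs innovations with a 3×3
kernel.

What the generator does *not* emulate: dynamically consistent coupling
between variables (no ocean model), realistic coastline geometry, and
observation-error structure. A green test therefore establishes that the
*statistical machinery* is correct on data with the stated structure —
not that the published real-data numbers are reproduced; those derive
from proprietary-scale satellite/reanalysis/model inputs and are out of
reach at desk scale by design.

Two deliberate consequences of the stated world show up in tests. First,
event amplitudes are expressed in multiples of a per-variable σ unit
(`sigma_event`, defaulting to the noise sd) so a noise-free world keeps
physical amplitudes. Second, *sign-unbalanced* injected events leak into
the estimated climatology (each non-event year's MAM shifts by roughly
`Σ amp/n_years` with the opposite sign), which can push non-event springs
over the detection threshold — a real property of deseasonalized short
records, not a bug; recovery tests therefore either balance event signs
or assert exact recovery of the injected sign class only.

The exact-recovery acceptance test states its world a priori: six
half-sine events (3 low / 3 high so leakage cancels), duration 3,
amplitude 24× the cell noise sd, AR(1) φ = 0.2, 21 years. By the
generator's variance arithmetic the CDNI-mean series then has
σ ≈ 4.6 noise sd, so event peaks sit at ≈5σ ≥ 1.5σ and the noise at
≈0.22σ ≤ 0.3σ — inside the criterion's stated bounds, which the test
asserts on the realised series before asserting recovery.

## Pipeline and determinism

`run_pipeline()` executes generation → anomalies → CDNI series → events
(MAM peak filter) → composites with bootstrap masks (series and SST
maps; composites key to the low-NPP events) → budget composite, closure
and Q′/H′ → indices and a sliding correlation on a coarse all-ocean
global synthetic SST grid → filtered Hovmöller and a propagation-lag
estimate. Every stage output is serialized eagerly (CSV/JSON), and a
manifest records parameters, the seed and per-file MD5 hashes with paths
relative to the run directory. All randomness derives from the single
config seed (generator offsets, bootstrap offsets), so identical
configurations are byte-identical — acceptance criterion 8. Each stage
can be re-run standalone from the previous stage's serialized output;
`inst/cli/upwell.R` exposes the stages as subcommands.

## Known limitations

- Coastal-band geometry is a longitude-offset interpretation; a
  perpendicular-distance or isobath-bounded band would need bathymetry.
- The bootstrap offers no field-significance control across cells.
- `highpass_fft()` requires gap-free series; gaps must be filled or the
  segment split upstream.
- Sequential `remove_linear_trend()` + `deseasonalize()` differ from the
  joint fit by the documented cross-term; use `detrended_anomalies()`
  when exact nulling matters.
- The propagation-lag estimator assumes a single dominant signal; with
  weak waves under strong noise (the default world) the estimate is
  noisy — the acceptance criterion uses the noise-free configuration.
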