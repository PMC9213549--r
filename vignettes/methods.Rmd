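---
title: "Methods: downscaling precipitation isotopes and estimating flux isotope ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downscaling precipitation isotopes and estimating flux isotope ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fluxiso` turns two kinds of observatory measurements into daily isotope
data products: biweekly precipitation-composite δ²H/δ¹⁸O into daily
ensembles, and multi-height tower gas profiles into daily δ²H/δ¹⁸O of
evapotranspiration and δ¹³C of net ecosystem exchange. This vignette is
the package's own account of the models, the parameters that matter, the
numerical choices, what the synthetic generator does and does not
emulate, and the known limitations.

## 1. Downscaling model

### Seasonal cycle

A biweekly composite series is modelled as a deterministic seasonal
cycle plus a zero-mean stochastic anomaly. The cycle is a harmonic sum

$$S(t) = c_0 + \sum_{k=1}^{K} A_k \sin\!\left(\frac{2\pi t}{\tau_k} + \phi_k\right),
\qquad \tau_k = \frac{P_0}{k},$$

fitted by ordinary least squares on the linearised
$a_k\sin + b_k\cos$ form and converted to amplitude/phase
($A_k = \sqrt{a_k^2+b_k^2} \ge 0$, $\phi_k = \mathrm{atan2}(b_k, a_k)
\in [-\pi,\pi]$). Defaults: $K = 2$ harmonics (annual + semiannual) and
$P_0 = 365.25$ d. Two harmonics capture the asymmetric seasonality seen
in most mid-latitude records without over-fitting series that may hold
only a few dozen composites; both are configurable
(`n_harmonics`, `base_period`). The fit is unweighted by default — the
composite is already an amount-weighted quantity — with an optional
amount-weighted fit (`weights =`). Missing composites are dropped, not
imputed, and fewer than $2K + 1$ observations is an explicit
"too few observations" failure so that a data-poor site is skipped
rather than silently extrapolated. Because the design includes an
intercept, residuals have exactly zero mean, which is what lets the
remainder be treated as a zero-mean stochastic signal.

### Scale ladder and daily target statistics

The de-seasonalised composites are aggregated over contiguous blocks
anchored at the record start, at scales {14, 28, 42, 56, 70, 84} d —
biweekly up to 12-weekly in biweekly steps. A block's tracer value is
the amount-weighted mean of its member windows and its precipitation is
their sum; blocks with zero precipitation are excluded (their composite
is undefined), and a trailing partial block is discarded. Fewer than 3
usable blocks at any scale aborts the site: it cannot support a trend
fit. Requiring the full ladder up to 84 d is what decides whether a
site is "downscalable" at all.

Each statistic (mean, sd, and the three Pearson correlations among P,
δ²H, δ¹⁸O) is regressed linearly against $\ln\tau$ and evaluated at
$\tau = 1$ d, i.e. at the fitted intercept. For standard deviations the
fit is $\ln(\mathrm{sd}) \sim \ln\tau$ whenever all observed sds are
positive, so a power law $\mathrm{sd}(\tau) = \sigma_1 \tau^{b}$
extrapolates to exactly $\sigma_1$. Log-scale linearity is the minimal
monotone choice for a quantity whose variance decays roughly
geometrically with averaging length; it is configurable in spirit (a
Fisher-z transform for the correlations is exposed via `fisher_z`,
default off, since the correlations here sit far from ±1 where the
transform matters). The daily target *means* are pinned at zero — the
anomaly is zero-mean by construction — and the fitted mean trend is kept
only as a diagnostic in the provenance table.

Numerical guards, all recorded in the provenance table:
extrapolated correlations are clipped to ±0.999 and sds floored at
10⁻⁶ ‰ so the copula correlation matrix can remain positive definite;
every clip/floor is observable as `adjusted != "none"`.

### Gaussian copula, conditional sampling

The dependence model is a Gaussian copula over (P, δ²H, δ¹⁸O) with the
three extrapolated correlations. The precipitation margin is the
empirical distribution of wet-day amounts with Weibull plotting
positions $i/(n+1)$ and linear interpolation (clamped to
$[1/(n+1), n/(n+1)]$ so normal scores stay finite); the two isotope
margins are normal with the extrapolated daily sds. On each wet day the
amount maps to a normal score $z_1$, and the isotope scores are drawn
from the exact conditional bivariate normal
$(z_2, z_3) \mid z_1 \sim N(R_{21} z_1,\; R_{22} - R_{21}R_{12})$.
Conditioning uses the day's own amount only: the anomaly is modelled as
purely stochastic, with no temporal autocorrelation in the sampled
term (see limitations).

If the three extrapolated correlations are mutually inconsistent the
matrix is repaired by alternating eigenvalue flooring (at 10⁻⁸) with a
unit-diagonal reset — a projection toward the nearest correlation
matrix. If the repair moves any correlation by more than 0.05 the site
fails with an "unrepairable" error: at that point the extrapolated
dependence is no longer trustworthy and the site is better skipped than
silently altered.

### Restoring seasonality and the residual correction

The order of the final steps is: sample anomalies → add the seasonal
cycle → residual-correct. The correction is additive: for each composite
window the difference between the observed composite and the member's
amount-weighted mean over the window's wet days is added to every wet
day in the window. After it, each member reproduces *every* observed
biweekly composite to machine precision — the pipeline's hard
constraint. Windows whose observed composite has no wet day in the
daily record cannot be corrected; they are skipped and reported
(`skipped_windows`). Ensemble member $m$ uses seed `base_seed + m`
(recorded in `member_seed`), so the whole ensemble is a pure function of
its inputs. Defaults: 100 members; trace threshold 0.25 mm/d (a day
below it is treated as dry everywhere: flags, weights, margins).

## 2. Miller–Tans flux estimation

Two-member mixing between background air $(C_b, \delta_b)$ and a
surface flux with ratio $\delta_s$ satisfies
$C\delta = \delta_s C - C_b(\delta_b - \delta_s)$, so OLS of $C\delta$
on $C$ (with intercept) estimates $\delta_s$ as the slope. The package
uses plain OLS — not orthogonal-distance or geometric-mean regression —
matching the simple-regression convention for this product; the
standard error of the slope, $s/\sqrt{\sum(x_i-\bar x)^2}$ with
$s^2 = \mathrm{RSS}/(n-2)$, is the published per-day uncertainty. The
equivalent Keeling formulation (δ vs 1/C; the intercept estimates
$\delta_s$) is provided as an independent cross-check and agrees
exactly on noise-free mixtures.

Observations are pooled unweighted across all measurement heights
within a calendar date (local-standard-time day of the timestamp, no
day-boundary smoothing) and one of three windows: `alltime`, `daytime`
(incoming shortwave ≥ 10 W m⁻², the standard eddy-covariance
convention, inclusive on the day side), `nighttime` (< 10). Records
without shortwave contribute to `alltime` only. A regression needs
$n \ge 3$ and non-degenerate concentration variance; otherwise the day
gets no estimate. Units of the mixing ratio cancel in the slope, so any
consistent concentration unit works. No low-humidity screening is
applied by default; water-vapor analysers are known to deviate at low
dry mole fractions (≲ 5000 ppm), and users who need a screen can filter
the record table before calling the fit.

## 3. Quality flags

Precipitation site-days: 0 = precipitation at or above the trace
threshold (the 0.25 mm boundary itself passes), 1 = no data,
2 = trace. Flags 1 and 2 force the −9999 fill.

Flux estimates, precedence 1 > 2 > 3 > 4 > 0: 1 = no estimate (fill
−9999), 2 = $n \le 5$, 3 = $R^2 < 0.9$, 4 = slope beyond the Tukey
fences $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, else 0.
Choices that needed deciding:

* At $n = 5$ the published rules overlap ("$n \le 5$" is flagged low-n,
  "$n \ge 5$" is good); precedence resolves the boundary in favour of
  flagging — conservative and stated here.
* The fence context is the *flux series itself* (per site × window ×
  tracer), restricted to estimates with $n > 5$ and $R^2 \ge 0.9$; with
  fewer than 4 qualifying values there is no IQR context and no
  outlier flag is assigned.
* Quantiles are type-7 (linear interpolation), stated for
  bit-reproducibility. A slope exactly on a fence is *inside* it.
* Flag-2 and flag-3 estimates keep their numeric value on disk; only
  flag 1 maps to −9999.

## 4. File layout

Wide matrices: one row per calendar date (ISO-8601, contiguous across
the union of site records), one column per four-letter site code.
Values are written with 6 significant digits; −9999 is written
literally, and metadata flags are integers (never `1.0`). Precipitation
products: `daily_p_{d2H,d18O}_{mean,std}.csv` + `daily_p_metadata.csv`,
with optional per-member files. Gas products per tracer × window:
`daily_et_flux_d2H_alltime.csv` (… `d18O`, `nee_flux_d13C`; `daytime`,
`nighttime`), each with `_error` (slope SE) and `_metadata` companions —
27 files. A single-member ensemble writes std 0 (not −9999) on wet
days, since the day has a valid value.

## 5. The synthetic generator

`simulate_precip_site()` emulates the downscaler's input family with
known truth: wet-day occurrence by a two-state Markov chain
(P(wet|dry) = 0.45, P(wet|wet) = 0.65 → stationary wet fraction 0.56, a
humid site), gamma depths (shape 1.2, mean 6 mm), and wet-day anomalies
built from a pair of fractional-Gaussian-noise processes (Hurst 0.85)
blended with the normal score of the day's amount to hit the target
correlations: ρ(δ²H, δ¹⁸O) = 0.95, ρ(δ, P) = −0.3. Seasonal sinusoids
(amplitudes 4 ‰ δ¹⁸O / 32 ‰ δ²H, summer maximum) and means (−10 / −70
‰) sit on the meteoric-water-line ratio of 8. These are plausible
round numbers for testing, not any site's climatology. Long-memory
(Hurst-type) persistence is deliberate: the scale-extrapolation step
presumes that window statistics follow an approximate power law in the
aggregation scale, which holds for persistent hydroclimatic anomalies
but *not* for day-to-day-independent noise; a generator with iid
anomalies would violate the method's own applicability conditions.
Biweekly composites are derived from the daily truth by exact
amount-weighted averaging, so the generator's outputs satisfy the
downscaler's input contract by construction.

`simulate_tower_site()` emits multi-height records that satisfy the
two-member mass balance exactly (background CO₂-like defaults, a slowly
drifting source ratio, gamma concentration enhancements that are larger
at lower heights, a 06:00–18:00 sinusoidal shortwave curve peaking at
800 W m⁻², optional iid delta noise). With zero noise the Miller–Tans
slope recovers the source ratio to round-off, giving exact oracles.

What passing tests on these fixtures do **not** show about real data:
real records carry calibration drift and bias (calibration is upstream
and out of scope here), non-two-member mixing conditions (entrainment,
advection, storage), non-Gaussian anomaly dependence, humidity-dependent
analyser error, and precipitation occurrence/depth structures richer
than Markov-gamma.

## 6. Problem sizes and tolerances in the shipped checks

The test suite exercises the full chain at 3 synthetic years with 100
ensemble members (≈ 1.5 s per run), plus 8-member ensembles for the
structural checks; Monte-Carlo checks of the copula use 10⁵ draws.
Identities are asserted at machine-level tolerances (residual
correction ≤ 10⁻⁹ ‰, regression oracles ≤ 10⁻¹⁰, mixing identity ≤
10⁻⁸ ‰); statistical recoveries use Monte-Carlo bands (copula
correlation ±0.02 at 10⁵ draws; end-to-end daily-sd within 25 %,
cross-correlation within ±0.1, seasonal amplitude within 15 % at the
fixed test seed).

## 7. Known limitations

* **Daily-sd extrapolation bias.** For intermittent precipitation, the
  amount-weighted window statistics do not follow a single power law
  all the way to 1 d: the effective number of wet days per window
  distorts the small-scale end. Extrapolating the 14–84 d trend
  therefore tends to *overestimate* the daily anomaly sd — typically by
  a few tens of percent on this generator's conditions, varying
  realization to realization. The biweekly composites are reproduced
  exactly regardless (the residual correction is a hard constraint);
  the caveat applies to the day-to-day spread inside each window, and
  the ensemble std files quantify exactly that spread.
* **Correlation-trend noise.** With ~78 biweekly windows the ladder
  correlations are noisy; occasionally the extrapolated triple is
  mutually inconsistent beyond repair and the site fails (by design)
  with an "unrepairable" error, the analogue of a real site that cannot
  support the method.
* **No temporal autocorrelation in sampled anomalies.** Conditioning is
  per-day; consecutive wet days are conditionally independent given
  their amounts, so storm-scale persistence in the *output* comes only
  from the seasonal cycle and the residual correction.
* **Post-correction correlation.** The residual correction can perturb
  the sampled δ²H–δ¹⁸O correlation slightly; the realised value is
  exposed through the ensemble members for diagnosis rather than
  re-imposed.
* Calibration to VSMOW/VPDB, humidity corrections, flux magnitudes,
  storage/advection terms and data retrieval are all upstream or out of
  scope.
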