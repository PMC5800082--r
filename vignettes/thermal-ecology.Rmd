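---
title: "Thermal ecology of a container-breeding mosquito: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal ecology of a container-breeding mosquito: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosqtherm)
library(dplyr)
```

mosqtherm analyses how temperature shapes the life history of a
container-breeding mosquito such as the Asian bush mosquito
(*Aedes japonicus japonicus*), and turns laboratory rearing data into two
distribution-relevant maps: the potential number of generations per year,
and the frequency of larval-lethal frost events. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical
choices made where the design was genuinely open.

## Egg cold tolerance

Eggs exposed to sub-zero temperatures hatch less the longer the exposure.
For each exposure temperature, the mean hatch success (percent of eggs
from which larvae fully detached within three days of the flooding
stimulus, averaged over replicate cups) is regressed on exposure duration
`x` (days) with two candidate families:

* exponential decay, `y = A exp(-k x) + c` — hatch declines to a floor
  `c`, the asymptotic **minimal hatch success**;
* logistic decline, `y = L / (1 + B exp(r x))` — hatch collapses towards
  0 (for `r > 0`).

Both are fitted by nonlinear least squares **on the percent scale** and
the family with the lower AIC is kept, ties going to the exponential.
Percent-scale fitting is the only convention consistent with asymptotes
reported in percent; the arcsine-square-root transform is used only in
the hypothesis test of an exposure-length effect (`exposure_effect_test()`,
a regression F-test on per-duration means). An `transform = "arcsine"`
flag switches the residual scale for the fits if desired.

Numerical choices:

* AIC for a least-squares fit is `n log(RSS/n) + 2(p + 1)`, counting the
  residual variance as a parameter — the standard NLS convention.
* Start values are scale-free: `A` = range of `y`, `k` = 1/median(`x`),
  `c` = min(`y`); the logistic starts from `L = 1.05 max(y)`, `r = 1`,
  with `B` solved from the first point.
* The logistic is optimised in the reparameterisation
  `y = D / (exp(r x) + s)` with `D = L/B`, `s = 1/B`. When hatch is far
  from saturation, `B` is enormous (the fitted −9 °C curve has
  `B ≈ 7 × 10⁸`) and only `D` and `r` are sharply identified; optimising
  `(L, B)` directly stalls, while `(D, r, s)` is well conditioned. The
  result is converted back to `(L, B, r)` for reporting.
* A constant series leaves the decay rate unidentifiable; the fit is
  flagged `degenerate` and the asymptote is reported as the mean.

`minimal_hatch()` truncates (not rounds) the asymptote to a whole
percent, matching how such floors are conventionally quoted (36.12 → 36,
10.67 → 10).

### What the recovery simulations show

With the default design (10 durations from 0 to 14 days, 5 cups of 20
eggs) the per-duration binomial standard error is about 5 percentage
points. Under these conditions the least-squares asymptote is a slightly
biased estimator: over 200 replicate simulations from the 0 °C truth
curve the mean fitted `c` sits roughly half a percentage point below the
generating 36.12, so the truncated recovery can land on 35 rather than
36. This is a property of the estimator under the experiment's noise, not
of the optimiser (the same minima are found by an independent optimiser
from truth-based starts), and we deliberately do not enlarge the
synthetic experiment to hide it.

## Life-trait summaries and tests

Mortality is computed per cup and averaged over the (default five) cups
of a treatment, because replicate-level dispersion is a cup-level
quantity. Tests follow the classical toolkit: one-way ANOVA and pairwise
Welch t-tests with Bonferroni correction on arcsine-square-root
transformed per-cup mortality; an exact two-sided binomial test of the
adult sex ratio against 1:1, pooled over cups per temperature; two-way
ANOVA (temperature × sex) on R1 wing-vein length.

For the body-size analysis on the *percent difference to the maximal
length* scale, the reference maximum is the largest per-temperature mean
length within each sex, not the single largest individual — a noisy
extreme would contaminate every normalised value. Even so, the reference
is estimated, and its error shifts each sex's normalised values by an
independent amount. That shift and the residual noise scale together, so
the inflation of the sex term's type-I rate does not vanish with more
data: with a simulated-null sex effect the sex term stays non-significant
in roughly 85% of replicates, not the nominal 95%. Conclusions drawn from
this scale should therefore lean on effect sizes (the sex F statistic
collapses by an order of magnitude relative to the raw-length analysis)
rather than on the exact p-value.

Ages at pupation, emergence and adult death are summarised as
per-temperature means and fitted with `age = A exp(-k T) + c` (days) by
nonlinear least squares; `k > 0` encodes faster development at warmer
temperatures and `c` the high-temperature floor.

## Thermal performance and cardinal temperatures

The performance measure is **cumulative female survival**: the
proportion of larvae surviving to adulthood multiplied by the female
developmental rate (1 / mean female age at emergence, day⁻¹).
Temperatures with no emerged females contribute performance 0 — those
zeros carry the information that locates the lower limit, so they stay in
the fit.

The candidate zoo in `fit_model_zoo()` holds five models: Brière-1 with
free shape `m`, Brière-1 with `m = 2` fixed, a truncated quadratic, a
Gaussian, and a linear model with a lower threshold. Each is fitted by
Levenberg–Marquardt least squares with multi-start initialisation
(`T_min` = coldest positive-performance temperature − 2 °C, `T_max` =
warmest + 2 °C, scale from the peak; `m` started at 1, 2 and 4), and the
candidates are ranked by Akaike weights. Non-converging candidates get
infinite AIC and zero weight instead of aborting the selection.

The Brière-1 curve

$$y = a\,T\,(T - T_{min})\,(T_{max} - T)^{1/m}$$

is zero at both limits and positive between them; the optimum `T_opt` is
the unique root of `dy/dT = 0` on `(T_min, T_max)`, found by bracketed
root-finding on the analytic derivative. This agrees with the closed-form
quadratic root

$$T_{opt} = \frac{2 m T_{max} + (m+1) T_{min} +
  \sqrt{4 m^2 T_{max}^2 + (m+1)^2 T_{min}^2 - 4 m^2 T_{min} T_{max}}}{4m + 2}$$

to the root-finder tolerance (10⁻⁹ °C by default), and `T_opt` is exactly
invariant to the scale constant `a`. With the published parameters
(`a = 6 × 10⁻⁶`, `m = 2`, limits 7 and 31 °C) the optimum is 25.61 °C,
i.e. 26 °C to the nearest degree.

```{r topt}
briere1_topt(m = 2, t_min = 7, t_max = 31)
```

## Generation time and voltinism

The emergence-age fit, shifted by a fixed pre-oviposition period
(`shift_days = 14`: time from adult emergence to first oviposition,
folded into the asymptote), gives the generation-time model

$$G(T) = A e^{-kT} + c \quad \text{days},$$

with defaults `A = 290.75` d, `k = 0.17` °C⁻¹, `c = 22.32` d. `G` is
treated as a **time in days** — the only dimensionally consistent
reading — and potential generations accumulate month by month:

$$N = \sum_{m=1}^{12} \frac{d_m}{G(T_m)},$$

with `d_m` the real-calendar month lengths of a 365-day year. At a
constant 25 °C this gives `365 / G(25) ≈ 13.8` generations. Two
deliberate choices:

* **No low-temperature cutoff by default.** `G(T)` is evaluated even
  below the 7 °C developmental minimum, where contributions are
  negligible but non-zero; `t_cutoff` enables a sensitivity analysis that
  zeroes sub-threshold months.
* **Monthly blocks, not daily interpolation.** Accumulation uses the
  monthly mean directly; the sum is exactly additive over any partition
  of the year into temperature-constant blocks.

Gridded inputs are long tibbles (`x`, `y`, `month`, `temp_C`) with plain
CSV serialisation, including a `scale_factor` flag for tenth-degree
integer packing. `voltinism_map()` applies the accumulation per cell,
propagates missing months as no-data, and attaches a mean/min/max
summary; `scenario_temperatures()` midpoints monthly minimum and maximum
layers of a climate scenario ((tmin + tmax)/2, the natural combination
when no rule is given); `extract_points()` uses nearest-cell lookup,
matching common raster-extraction defaults at coarse cell sizes, and
flags out-of-extent points rather than extrapolating.

## Frost events

A frost event is a maximal run of at least `min_run_days = 3` consecutive
days at or below `threshold = 0` °C on the **daily mean** temperature
(the conventional gridded daily variable; the comparison is inclusive).
An event counts once regardless of length — the biological reading is
that a larval cohort dies once. Declared date gaps and missing values
split candidate runs; a run spanning a year boundary belongs to the year
it starts in; the per-year average divides by the exact span in days /
365.25, so leap days in real data are handled naturally.

One property worth spelling out: cooling a series (or raising the
threshold) never destroys an event, but it can **merge** two adjacent
events into one, so the raw event count is not monotone. The invariant
that holds — and that the tests assert — is containment: every original
event interval lies inside an event of the cooled series, and the total
number of frost days is monotone.

## The synthetic-data generator

The generator produces all four input kinds with the statistical
structure the analysis assumes, so the full pipeline runs with no
external downloads. Its defaults are the study conditions: 16 rearing
temperatures × 5 cups × 40 larvae; 4 exposure temperatures × 10
durations (0 to 14 days, hour-scale exposures as fractional days) × 5
cups × 20 eggs; and the fitted curves above as generative truth.

* **Hatch**: per cup, `Binomial(20, curve(duration)/100)`; truth curves
  that leave `[0, 100]`% are rejected up front.
* **Survival**: the analysis only defines the product
  survival × developmental rate, so the generator must pick a
  factorisation; it divides the Brière performance curve by the
  developmental rate (equivalently multiplies by the emergence age) and
  clamps to `[0, 1]`. Expectation of the reconstructed performance then
  reproduces the truth curve exactly, and temperatures outside the limits
  yield no survivors by construction.
* **Ages**: multiplicative lognormal noise with mean 1 and CV 0.1 on the
  pupation age and on the positive stage gaps, so survivor ages are
  strictly ordered pupation < emergence < death and mean emergence age
  tracks the truth curve. The pupation and adult-death truth curves are
  not published; the defaults (`240 e^{-0.17T} + 5.8` and
  `360 e^{-0.17T} + 20` d) are plausible envelopes around the emergence
  curve, chosen once, sharing its decay rate so the stage ordering holds
  at every temperature.
* **Sexes**: Bernoulli(0.5); individuals are independent — within-cup
  correlation is not modelled because no replicate-level correlation
  estimate is available.
* **The 5 °C hatch control** is a flat 87% curve (exposure at 5 °C does
  not reduce hatch; the level is a typical non-freezing hatch success).
* **Wing length**: linear in temperature (4.26 mm at 15 °C falling to
  3.04 mm at 31 °C for females, males 0.4 mm smaller), CV 0.05.
* **Climate**: monthly grids are a latitude-graded annual mean with a
  sinusoidal cycle peaking in July (Germany-like defaults: mean 9 °C,
  half-amplitude 9 °C); daily series add AR(1) noise (lag-1 0.7, sd 3 °C)
  to the sinusoid, 365 days per year.

What the generator does **not** emulate: diurnal and inter-annual
temperature fluctuation, within-cup correlation, spatially correlated
climate noise, coastlines/topography, and any non-thermal driver. Tests
passing on synthetic data therefore demonstrate that the estimators
recover known truth under the experiment's noise structure — not that the
biological conclusions transfer to field data.

## Problem sizes and determinism

Every simulator takes an explicit integer seed and is bit-reproducible
under it. The recovery studies use 200 replicates (egg-curve recovery and
family selection; Brière parameter recovery at 5% relative noise, where
medians recover all four parameters within 10% and the optimum within
0.5 °C); the frost oracle comparison uses 1,000 random series; voltinism
map properties are exercised on grids up to 100 × 100 cells. These sizes
give Monte-Carlo standard errors comfortably below the tolerances being
asserted while keeping a full run inexpensive.

## Limitations

* Nation-scale results quoted from external climate layers (mean
  generations per year, frost-event maps for a real country) require
  those layers; with synthetic climate the package checks plausibility
  envelopes and structural properties (crop-commutation, warming
  monotonicity, containment) instead.
* Ages are measured from day 0 with larvae up to 24 h old at start, so
  development times inherit a slight underestimate from the source data
  convention.
* The pre-oviposition shift (14 days) is a fixed constant, not an
  estimated, temperature-dependent quantity.
* The two-way ANOVA on the percent-difference scale has the reference
  inflation discussed above.
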