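---
title: "Attributing preterm births to heatwaves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing preterm births to heatwaves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatptb)
```

## The problem

Exposure to heatwaves during the final week of gestation raises the risk of
preterm delivery (PTB, birth before 37 completed weeks). Given a gridded
daily maximum temperature record, province-level demographic tables, and a
relative risk (RR) for last-week heatwave exposure, `heatptb` estimates how
many PTBs heatwaves cause each year, how much of that burden is due to
anthropogenic climate change, and what the downstream human-capital and
economic consequences are.

The pipeline has seven stages:

1. **Exposure field.** Daily tmax per 0.5-degree-style grid cell, either
   supplied or generated synthetically.
2. **Heatwave detection.** A heatwave is a run of two or more consecutive
   days with tmax strictly above the cell's 90th percentile of warm-season
   (May--October) temperatures pooled over the study period. Runs are
   detected on the full series, so events may straddle month boundaries;
   only warm-season days can accrue burden later, because the baseline is
   only defined there.
3. **Exposure window.** Delivery day $d$ is *exposed* when at least one
   heatwave day falls in $[d-6, d]$, the final gestational week. We read
   "at least one heatwave event in the window" as "at least one heatwave
   *day* in the window": an event need not lie wholly inside the week for
   the mother to have experienced it, which is the epidemiologically
   meaningful exposure.
4. **Baseline and attributable burden.** The expected PTB count for cell
   $g$ in warm-season month $m$ of year $y$ is
   $\mathrm{basePTB}_{g,m} = \mathrm{Pop}_{g,y}\,\mathrm{BirthRate}_{g,y}\,
   \mathrm{PTBrate}_{g,y}\,\mathrm{BirthMon}_{g,m}$,
   spread evenly over the month's days. On exposed days the attributable
   fraction is $\mathrm{AF} = (\mathrm{RR}-1)/\mathrm{RR}$ and the
   attributable count is $\mathrm{aPTB}_{g,d} =
   \mathrm{basePTB}_{g,d}\cdot\mathrm{AF}$; on unexposed days AF $= 0$.
   With the default RR of 1.19, AF $= 0.159664$.
5. **Scenario differencing.** The same accounting runs on a factual
   (all-forcings) and a counterfactual (natural-forcings-only) climate
   ensemble; the member-wise difference is the burden attributable to
   anthropogenic climate change.
6. **Monte Carlo uncertainty.** RR imprecision is propagated by sampling
   ln RR; scenario intervals additionally pool the climate-model spread.
7. **Human capital.** Annual attributable PTBs cascade into additional
   cases of later-life outcomes, lost IQ points, and monetized costs.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `warm_months` | May--Oct | months | season where baselines (and thresholds) are defined |
| `percentile` | 0.90 | — | heatwave threshold quantile of warm-season tmax |
| `min_duration` | 2 | days | minimum consecutive exceedance run |
| `window_days` | 7 | days | final-gestational-week exposure window |
| `rr`, `ci` | 1.19 (1.09--1.29) | — | last-week heatwave RR for PTB (an input, estimated elsewhere from a national birth cohort) |
| `n_draws` | 1000 | — | Monte Carlo coefficient samples |
| `ptb_growth` | 1.013 | /yr | annual growth of the national PTB rate |

Exceedance is strict (`tmax > threshold`): "exceeding" is read literally,
so ties at the threshold are non-events. All quantiles — thresholds and
empirical confidence intervals alike — use linear interpolation between
order statistics (type 7), recorded in output metadata because no single
convention is universal.

## Bias correction and the threshold choice

Simulated series are calibrated by empirical quantile mapping per cell and
calendar month: the map pairs the simulated and observed quantiles (99
anchors by default) over their common period, interpolates linearly
between anchors, and extrapolates linearly from the two outermost anchors
— clamping would censor exactly the upper tail where heatwaves live. The
map is fitted on the *factual* run and applied unchanged to its paired
counterfactual run; the counterfactual is never calibrated against
observations directly, otherwise the correction itself would absorb part
of the anthropogenic signal.

For the same reason, heatwave thresholds for both scenarios of a given
model are computed once from that model's bias-corrected factual series.
A scenario-specific threshold would, by construction, give both scenarios
the same exceedance rate and erase the attribution signal.

## Uncertainty model

Only one coefficient — the log RR of last-week heatwave exposure — enters
the burden formula, so multivariate-normal coefficient sampling collapses
to a univariate normal on $\ln RR$ with
$\mathrm{sd} = (\ln 1.29 - \ln 1.09) / (2 \times 1.959964) \approx 0.0430$
recovered from the printed 95% CI. One draw applies to every cell and day
of a replicate (the RR is a single national parameter). Because the burden
is linear in AF, each draw rescales the stored exposed-baseline mass
without re-running detection, which keeps 1000-draw intervals essentially
free. Observed-climate intervals are percentile intervals over draws;
scenario intervals flatten draws x models. Only RR uncertainty is
propagated: baseline demographic inputs and the human-capital parameters
carry no uncertainty model here, so intervals should be read as
exposure-response uncertainty conditional on the baselines.

## The human-capital cascade

For each countable outcome (neonatal death, child asthma, T1D, T2D, ASD,
ADHD) with population prevalence $P$, PTB-group relative risk $RR_o$ and
national PTB rate $P_{ptb}$, the incidence among preterm births solves
$P = P_{ptb} I_e + (1-P_{ptb}) I_e / RR_o$, and additional cases are
$N_{add} = \mathrm{nPTB} \cdot (I_e - P)$. Reduced IQ instead multiplies
lost points per preterm child by the attributable count. Costs are
$N \times$ unit cost; the human-capital total sums outcomes flagged for
inclusion (neonatal death is excluded by convention, and the direct PTB
cost is reported separately). The cascade is exactly linear in nPTB, so
CI bounds pass through the same formulas. Unit costs keep a currency-year
tag and are summed as given — mixed currency years are flagged, not
inflation-adjusted.

The packaged outcome panel (`outcome_specs_synthetic.csv`) is a clearly
labelled placeholder with the right structure; substantive analyses must
supply evidence-based RRs, prevalences and unit costs. A published
reference table for China (`human_capital_reference()`) ships for
arithmetic cross-checks of the summation machinery.

## What the synthetic generator emulates — and what it does not

Each cell's tmax is an annual sinusoid (default 18 ± 12 degC peaking near
day 196) plus stationary AR(1) Gaussian noise (sd 3 degC, lag-1
autocorrelation 0.7 — enough day-to-day persistence to produce multi-day
exceedance runs), plus, in factual and observed series only, a linear
anthropogenic ramp (default 0.3 degC per decade, a realistic recent
warming rate). Noise substreams derive from (member, cell) only, so
factual and counterfactual members of the same index share natural
variability exactly and their difference isolates the trend; the observed
series has an independent stream. Demographic tables use a first-year
national PTB rate of 0.07 growing at 1.3%/yr, birth rates near 11 per
1,000, and Dirichlet-like monthly birth proportions normalized to 1.

Deliberately absent: spatial covariance between cells (all downstream
math is cell-wise), non-Gaussian temperature tails, real geography or
GCM physics, and non-standard model calendars (all series use the
proleptic Gregorian calendar). Passing tests therefore demonstrate the
correctness of the accounting and the attribution logic under the assumed
statistical structure, not fidelity to any particular reanalysis.

## Numerical and design choices

- **Provinces** partition cells contiguously by index; since province
  values are applied uniformly to member cells, any partition is
  equivalent.
- **Burden accrual**: only warm-season calendar days carry baseline, so
  an exposed November day contributes nothing; heatwave days outside the
  warm season are still detected and kept.
- **Year assignment** of an attributable case is the calendar year of the
  delivery day.
- **Live-birth denominator** for per-million rates is
  $\sum \mathrm{Pop}\cdot\mathrm{BirthRate}$ over the year and region.
- **Warm-season share** uses the baseline PTB total as denominator (the
  model has no observed PTB counts).
- **Anthropogenic proportion** is computed on ensemble means of numerator
  and denominator, not the mean of per-member ratios, which is unstable
  when a member's factual burden is near zero; zero-denominator years are
  reported as missing.
- **Degenerate quantile maps** (a constant simulated month) collapse to a
  constant shift.
- **Determinism**: every stochastic step derives from one master seed;
  rerunning a configuration reproduces byte-identical tables, and the run
  manifest (seeds, parameters, file checksums) suffices to reproduce a
  run.

## Problem sizes used in the tests

The shipped tests exercise the pipeline at desk scale: unit fixtures of
1--8 cells; oracle-equivalence sweeps over 1,000 random series of up to
400 days; a 20-member, 6-year null-attribution experiment; 100-member
ensembles for trend-recovery checks; 200-replicate coverage simulations
with 400 draws each; and an acceptance run with 16 cells, 4 provinces,
11 analysis years, 5 members and 1000 draws. These sizes give stable
Monte Carlo checks while keeping the whole suite fast; the statistical
conclusions they support do not depend on scaling further.

## Known limitations

- The RR is treated as a single national parameter; no region-specific
  exposure-response heterogeneity.
- No harvesting/displacement adjustment, humidity or pollution
  covariates, or gestational-age-resolved survival modelling.
- Human-capital outcome parameters carry no uncertainty; Table-style CI
  columns scale the attributable-PTB interval through the same linear
  formulas.
- Grids, masks and maps serialize to plain-text CSV; no NetCDF I/O.

## A minimal run

```{r, eval = FALSE}
cfg <- run_config(
  climate = climate_config(n_cells = 16, n_provinces = 4,
                           years = 2006:2020, n_members = 5, seed = 1),
  years = 2010:2020)
res <- run_pipeline(cfg, out_dir = "run1", verbose = TRUE)
res$comparison            # anthropogenic share of the heatwave-PTB burden
res$ci_observed           # Monte Carlo intervals, observed climate
res$human_capital         # downstream cases, IQ points, costs
```
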