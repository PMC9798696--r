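---
title: "Null movement models and pseudo-absence selection testing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null movement models and pseudo-absence selection testing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudotrack)
```

## The inference problem

Electronic tags tell us where a marine animal was, never where it was not.
To decide whether a tracked animal *selects* an environmental condition —
here sea-surface temperature (SST) — we compare the SST distribution along
its track with the SST an *environmentally naive* organism would have
sampled: a simulated walker with similar movement characteristics but no
access to the environment.  Those simulated tracks are **pseudo-absences**.
Selection is declared when the presence SST distribution is shifted,
one-sidedly, relative to the pseudo-absence distribution.

This vignette documents the modelling choices, tunable parameters, and
numerical conventions, and what the bundled synthetic ocean can and cannot
establish about real data.

## The four null movement models

All four models draw, at each daily step, a step length and a bearing, and
advance the position along a great circle (sphere of radius 6371.0088 km —
the IUGG mean radius; at basin scales the spherical error is below 0.5%).

* **Brownian motion** — bearing uniform on (−180°, 180°]; step length drawn
  from a lognormal whose log-mean and log-sd are the *monthly* moments of
  `ln(step)` of the observed tracks.  Observed step lengths are strongly
  right-skewed, so moments are fitted on the log scale; sampling on that
  scale also guarantees positive steps.  A zero-truncated Gaussian on the
  natural scale is available as an option (`brownian_dist = "truncnorm"`).
* **Truncated Lévy flight** — bearing uniform; step length from the
  truncated power law `p(l) ∝ l^(−μ)` on `[l_min, l_max]`, sampled by exact
  inverse-CDF.  Truncation makes the variance finite, so μ only needs to be
  positive.  Defaults: μ = 2, `l_min` = 1 m, and `l_max` = 3× the 99.5th
  percentile of the observed steps; all three are configuration values
  recorded with the outputs, since there is no canonical choice.
* **Correlated random walk (CRW)** — turning angle and step length drawn
  independently from the month's *empirical* samples; the turning angle is
  added to the current heading, giving directional persistence.
* **Joint CRW (JCRW)** — the pair (turning angle, step length) resampled
  jointly from observed pairs, preserving the long-step/small-turn
  correlation.  Exact pair resampling was chosen over a smoothed 2-D
  density: it is faithful to the observed joint support and introduces no
  bandwidth parameter.  (First steps of a track have no defined turning
  angle, so the JCRW's step marginal is the set of steps that carry an
  angle.)

**Time gaps.**  Tracks may miss days.  Brownian and Lévy steps over a gap
of Δt days are rescaled by √Δt (diffusive scaling of displacement); the
CRW/JCRW instead repeat daily draws across the gap, because a √Δt rule is
only meaningful for isotropic diffusion.  Steps spanning more than one day
are excluded from the fitted monthly statistics by default — they conflate
multi-day displacement with daily movement.

**Monthly restarts.**  A free-running null walker eventually samples an
ocean the animal never saw (inflating differences: an unreasonably loose
null), while a null restarted too often mimics the animal itself (an
over-specified null).  The compromise used here restarts every simulated
track at the observed animal position at the start of each calendar month:
the first segment starts at the deployment fix, later segments at the fix
dated the 1st, or the earliest fix of that month when the 1st is missing.
Headings do not carry across restarts — segments are independent
month-long simulations.  Pseudo fixes are date-aligned one-to-one with the
source track.

**Empty months.**  If a simulation needs a month with no fitted data, the
sampler falls back to the all-month pool and warns.  With seasonally
structured data, supply data covering the simulated months instead.

## Synthetic presences with known selection strength

To measure error rates we need tracks whose selection strength is *known*.
The biased random walk takes fixed 50 km daily steps for 80 days (a typical
pelagic-predator track length); at each step it finds the bearing of the
warmest SST cell within a 50 km radius and draws its turning angle from a
Von Mises distribution centred on that bearing *relative to the current
heading* (the draw is a turning angle, consistent with the CRW framing).
The concentration κ sets selection strength: κ = 0 is a uniform circular
distribution (no selection); κ = 20 turns almost directly toward warm
water.  The canonical grid is κ ∈ {0, 0.25, 0.5, 0.75, 1, 2, 5, 10, 20}
with 100 tracks per κ.  When the SST search fails (cloud gap, domain edge)
the walker keeps its heading (Von Mises centre 0°).  Synthetic positions
are treated as exactly known, so SST is sampled at the containing cell.

Start positions for cohorts are drawn uniformly from the central half of
the field's domain (configurable, or fixed), leaving room to roam before
reaching a boundary.

## Matching tracks to gridded SST

SST fields are daily lat/lon grids (nominally ~9 km) with missing cells.
Following standard satellite practice, an 8-day *backward* rolling mean
(mean of available values over days t−7…t, per cell) increases coverage;
a cell stays missing only when the whole window is.

Sampling is nearest-cell, not bilinear: the analysis treats SST as point
values on the grid, and nearest-cell keeps missingness semantics simple.
Exact midpoints go to the lower index, making the lookup deterministic.

Real positions carry error.  With a 95% confidence radius `ci95_km`, the
positional error is modelled as an isotropic 2-D Gaussian with
σ = 0.25 × `ci95_km`, and the matched SST is the Gaussian-weighted mean of
non-missing cells within 3σ (98.9% of the mass; configurable).  When σ is
below half a cell the weighted sample degrades to the point sample.
Pseudo-absence fixes inherit the `ci95_km` of their date-matched presence
fix.  Fixes with no available SST are dropped and counted; dropped counts
are always reported.

## The one-sided KS test

With right-continuous ECDFs `F_p` (presence) and `F_a` (absence), the
warmer-direction statistic is `D = max(F_a − F_p)` over the pooled values
(floored at 0) — rejection means the presence CDF lies *below* the absence
CDF, i.e. presences sit at higher SST.  The colder direction is symmetric.
The p-value is the asymptotic one-sided two-sample formula
`p = exp(−2 D² mn/(m+n))`, capped at 1; sample sizes in this analysis are
large enough (tens to thousands) that exact small-sample computation is
unnecessary, and ties from discretised SST are handled deterministically by
the ECDF convention.  Outcomes are classified **warmer** / **colder** /
**both** / **none** from the two p-values at level α (default 0.05, with
Bonferroni α/k available).  By default the pseudo-absences of all simulated
null models are pooled into a single absence sample per test; per-model
testing is available.

Aggregation pools dated samples by calendar period across years (monthly,
bimonthly, quarterly, semiannual, yearly/all), mirroring seasonal analysis.

## The power harness

For each κ the harness simulates a presence cohort, fits monthly movement
statistics *from that cohort* (the nulls must share the presences' movement
characteristics; for observed animals you would fit them from the observed
tracks), simulates pseudo-absence cohorts, matches everything to SST, and
then, for each aggregation size k, draws random k-track subsets, pools
presence and absence samples, and runs both one-sided tests.  k = 1
enumerates every track exactly once (the per-track case).  An outcome is
*correct* when κ > 0 is classified "warmer", or κ = 0 is classified
"none".  Confidence intervals are percentile bootstraps (2.5/97.5%) over
the binary outcomes.  All per-test p-values are stored, so significance
thresholds can be swept afterwards without re-simulation.

Every random draw descends from one master seed through a stable string
hash of (component, track, model, replicate), so cohorts are reproducible
and order-independent.

## The synthetic ocean

The generator emulates the statistical structure the analysis relies on —
not ocean physics:

* a meridional gradient (default −0.35 °C per °lat, base 22 °C at the
  southern edge of a 20–45°N, 150–115°W domain);
* mesoscale anomalies: a smooth random field built from coarse-grid
  Gaussian noise with AR(1) temporal persistence, lightly smoothed and
  bilinearly interpolated (defaults 1.5 °C amplitude, 150 km / 20 day
  scales);
* a 2 °C seasonal sine, 0.2 °C white noise;
* clumped, cloud-like missingness (default 10%) by thresholding a second
  smooth field, so the realised fraction is exact per day.

With the stochastic amplitudes set to zero the field is an exact
deterministic function of day and latitude, which the tests exploit.

**What passing tests show.**  On this field the pipeline reproduces the
qualitative findings expected of the method: mean presence SST rises with
κ; strong selection (κ = 20) aggregated over ~10 tracks is detected at
p < 10⁻⁶; per-track tests at κ = 0 are wildly anticonservative (the
spatially and temporally autocorrelated field violates the independence
the KS p-value assumes); and the correct-classification rate grows toward
1 as tracks are aggregated.  **What they do not show:** absolute error
rates on real satellite SST — the synthetic field's gradient and eddy
statistics are only satellite-like, real tracks carry state-space
smoothing artefacts (regularised tracks are straighter than the true
path), and positional-uncertainty structure differs by tag type.  Rates
measured here are analogues, not predictions, of any particular dataset.

## Numerical choices and degenerate inputs

* Spherical geodesy throughout; bearings clockwise from north in [0, 360);
  turning angles in (−180, 180], positive clockwise.  The bearing of
  coincident points is an error, and zero-length steps are dropped during
  extraction (their bearing is undefined).
* Warmest-cell search: great-circle distances to cell centres, the cell
  containing the position excluded; ties broken by distance, then by the
  lowest (lat, lon) index — repeat calls are identical.
* Von Mises sampling uses Best–Fisher rejection; κ = 0 short-circuits to
  the uniform distribution.
* Lévy inversion is closed-form for μ ≠ 1 and μ = 1 (log branch); μ within
  10⁻¹² of 1 uses the log branch.
* Tracks shorter than 2 fixes, non-increasing dates, and out-of-range
  coordinates are validation errors naming the offending row.

## Simulation sizes used by the test suite

Checks are run at sizes chosen to make their statistical assertions stable:
Lévy ECDF checks at 10⁵ draws; KS calibration at 2000 replicates of
n = m = 500; Brownian diffusion at 4000 tracks × 100 steps; CRW/JCRW
marginal checks at ~10⁵ simulated steps; cohort-level checks at 50–100
tracks per κ with 10 pseudo-absence replicates per (track, model) — a
scaled-down cohort relative to the canonical 100, which leaves the pooled
absence samples large (thousands of points) while keeping the suite quick.
The same scaling applies to the acceptance script.  The synthetic-ocean
grid used by the simulation-study tests is coarsened to 0.25° (~28 km)
cells: the 50 km search radius spans several cells at either resolution,
and the grid resolution is a fixture size, not a modelling claim.

## Known limitations

* Monthly empirical distributions need data in each simulated month; the
  all-month fallback is a blunt instrument.
* The JCRW resamples observed pairs exactly; it cannot extrapolate beyond
  the observed joint support (copula-based alternatives are out of scope).
* The biased walk selects on a single variable at a daily scale within a
  fixed radius; multi-factor selection, memory, and advection are not
  modelled.
* Nearest-cell sampling ignores sub-cell gradients; at ~9 km resolution
  this is below the positional noise of most marine tags.
* The asymptotic one-sided p-value is anticonservative for very small
  samples (n ≲ 10); aggregation sizes here keep samples well above that.
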