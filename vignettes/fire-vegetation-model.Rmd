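---
title: "Modeling climate-driven wildfire in an individual-based boreal forest simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling climate-driven wildfire in an individual-based boreal forest simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firelarch)
```

## The system and the model

`firelarch` simulates the larch-dominated boreal forest of eastern Siberia
as a population of individual trees on a spatially explicit landscape,
coupled to a climate-driven wildfire module. The landscape couples a coarse
raster stack at 90 m resolution (elevation, slope, topographic wetness
index, water mask) with a 0.2 m fine sub-grid that carries the litter
layer, the permafrost active-layer depth, and per-species ground seed
pools. Each simulated year runs: fire weather, at most one stochastic fire,
tree demography (growth, seed production and dispersal, establishment,
natural mortality), then litter and active-layer dynamics.

The package is organized so that the wildfire module — the part with
quantitative, field-anchored structure — is exact and fully specified,
while the demographic core is a deliberately minimal stand-in whose rates
all live in the species trait table (`species_defaults()`); it can be
re-parameterized without code changes.

## Fire weather: from monthly climate to an ignition probability

A monthly fire probability rating is a linear model of monthly mean
temperature and precipitation sum, applied only to months above 0 °C
(frozen months carry no rating):

$$\mathrm{FPR}_{mon} = \beta_0 + \beta_T T_{mon} + \beta_P P_{mon},
\qquad \beta_T > 0,\ \beta_P < 0 .$$

Ratings are categorized with fixed thresholds — below 6.6 no fire weather,
6.6–7.0 mild, 7.0–7.46 severe, at or above 7.46 extreme; boundaries belong
to the higher class (the tie-break is a package decision; any consistent
convention works). The defaults for the coefficients are a documented
parameterization chosen so that a warm, dry month (20 °C, 20 mm) rates
near the extreme threshold; `refit_fpr_model()` re-estimates them from a
monthly fire-count series by ordinary least squares on `log1p(counts)`
(counts are strongly zero-inflated, and only the rating's quantiles matter
downstream, so any monotone transform of the counts is admissible).

The year's category counts $(n_{mild}, n_{severe}, n_{extreme})$ aggregate
to an annual ignition probability

$$\mathrm{FPR}_{ann} = \min\!\big(1,\ s\,(n_{mild} + 2\,n_{severe} +
4\,n_{extreme})\big),$$

a clamped weighted count: monotone, bounded in $[0,1]$, and tunable. The
weights (1, 2, 4) are a package choice (the aggregation's exact published
form is not available); the scale $s$ is *calibrated* by monotone bisection
so that the mean of $\mathrm{FPR}_{ann}$ over the forcing series equals a
target mean of 0.03 — on average one fire per ~33 years, the
paleoecologically supported rate for the region — to within $10^{-6}$.

## The fire engine

Each year one uniform draw against $\mathrm{FPR}_{ann}$ decides ignition
(at most one fire per year). A fire's center is uniform over the area and
its diameter is linear in the rating relative to the area width, so
$\mathrm{FPR}_{ann} = 1$ spans the whole area; the exponent of this law is
configurable (`diameter_exp`), linear being the simplest reading of
"extent determined by the rating relative to the width". Per fine cell,
intensity is the rating damped linearly by the local topographic wetness
index:

$$\mathrm{FI} = \mathrm{FPR}_{ann}\cdot
\max\!\Big(0,\ 1 - \frac{\mathrm{TWI} - \mathrm{TWI}_{min}}
{\mathrm{TWI}_{wet} - \mathrm{TWI}_{min}}\Big),$$

with a configurable wetness cutoff ($\mathrm{TWI}_{wet}$, default 80% of
the landscape TWI range above its minimum). Cells at or beyond the cutoff
burn at intensity zero and are excluded from the burned-cell count. Water
cells inside the disk receive intensity zero rather than blocking the fire
(no spread model exists to route around them). Fixed-scenario fires skip
the TWI mediation entirely so that a scenario labeled FI = 0.5 delivers
exactly 0.5 everywhere on land.

## Fire impacts

Tree death combines two independent hazards. Stem heating is attenuated
by bark insulation, with bark thickness proportional to height
($\mathrm{bark} = c_{bark}\,h$):

$$p_{stem} = \mathrm{FI}\cdot e^{-k_{bark}\,\mathrm{bark}} .$$

Crown damage uses flame (scorch) height $h_s = h_{max}\,\mathrm{FI}^{e}$:
the scorched fraction of the live crown enters as
$p_{canopy} = f_{scorch}^{\gamma}$, and
$p_{kill} = 1 - (1 - p_{stem})(1 - p_{canopy})$. Top-killed larches
resprout with a species-specific probability at 10% of their pre-fire
height; evergreens do not resprout.

The constants $(e, k_{bark}, \gamma) = (1.7, 1.5, 4)$ were calibrated — as
a joint package design choice — against the three qualitative fire regimes
the system is known for, and against nothing else:

* **FI = 0.1** (surface fire): flames of ~0.3 m kill seedlings and small
  saplings but leave the mature stem count without a visible response;
* **FI = 0.5**: survivable for tall larches (kill probability under a few
  percent above ~10 m) while removing the understory, followed by an
  establishment gain;
* **FI = 1.0**: stand-replacing; with $h_{max} = 15$ m above every
  attainable tree height, the crown scorch fraction is 1 and death is
  certain for every shipped species and height.

A sublinear plume-scaling exponent ($e \approx 0.4$) is physically
motivated for flame height as a function of fire-line intensity, but under
the constraint $h_{max} = 15$ m it yields ~6 m flames at FI = 0.1 and
wipes out the mature stand, contradicting the documented low-intensity
regime; the steeper default keeps the regime structure and remains
configurable.

Seeds on the ground are removed wherever intensity is positive; seeds in
cones are destroyed independently with probability equal to the tree's
local intensity (a tree uses the mean intensity of the fine cells its stem
footprint touches). Litter is reduced by the factor
$\max(0, 1 - \mathrm{FI}/\mathrm{FI}_{full})$ with complete removal at
$\mathrm{FI}_{full} = 0.8$.

## Litter and active layer

Litter regrows at 0.5 cm yr⁻¹ toward a cap of 18 cm. Independent
small-scale disturbances hit each fine cell with probability 0.045 yr⁻¹
and remove a uniform random fraction. The pair (cap, probability) was
calibrated once, by simulating the one-dimensional litter process alone,
so that the long-run spatial mean is ~13 cm, the field-observed
organic-layer height; with disturbances off, regrowth is exactly
deterministic (a property the tests assert).

The active layer follows a Stefan-type square-root law in the annual thaw
index $I$ (sum over months of $\max(T_{mon},0)\times 30.4$ °C days),
damped by litter insulation, and relaxes toward its equilibrium with a
3-year e-folding time:

$$\mathrm{AL}_{eq} = E\sqrt{I}\; e^{-k_{ins}\,\mathrm{litter}} .$$

$E = 2.24$ cm (°C day)$^{-1/2}$ and $k_{ins} = 0.013$ cm⁻¹ reproduce the
two anchor states of the system: ~60 cm under a cold-stage thaw index
(~1000 °C days) beneath 13 cm of litter, and ~100 cm under a warm-stage
index (~2000 °C days) on bare ground. Removing litter therefore deepens
thaw, which in turn gates establishment: Dahurian larch requires only
20 cm of thaw, Scots pine 100 cm, Siberian spruce and Siberian pine
200 cm — so evergreens can only invade where fire has stripped the
insulating litter.

## The demographic stand-in

The demographic core intentionally uses minimal forms; every constant is a
trait-table entry:

* growth $\Delta h = r\cdot s(T_{gs})\cdot (1+C)^{-1}$ with a Gaussian
  temperature suitability $s$ and a height-asymmetric competition index
  $C$ (sum over taller-or-equal neighbors within 10 m of neighbor height
  times a linear distance decay, computed exactly with a compiled bucket
  grid); heights are capped at a species maximum;
* seed production into a cone bank with binomial annual release, isotropic
  Gaussian dispersal (a deliberate simplification of wind-driven
  anisotropic dispersal, which is out of scope), plus a small Poisson seed
  rain from outside the area — without it, a whole-area stand-replacing
  fire (which zeroes ground pools and destroys every cone seed) could
  only recover through resprouts;
* establishment with per-seed germination probability
  $g_0\,e^{-k_{lit}\,\mathrm{litter}}\cdot s(T_{gs})$, gated by the
  species active-layer threshold, Poisson-drawn per cell and capped at one
  germinant per fine cell, species, and year (self-thinning within a
  0.04 m² cell);
* mortality $p = m_0 + (a/a_{max})^4 + m_C\,C/(1+C)$, certain beyond the
  maximum age.

Remaining demographic constants (`comp_scale = 0.012`, `m_comp = 0.25`,
`germ_base = 0.03`) were chosen once so that a fire-free stand under
stationary regional climate settles at a realistic ~0.09 stems m⁻²
(≥ 130 cm) with a continuous size distribution, and were not revisited.

## Synthetic forcing and landscape

`generate_synthetic_climate()` emulates the highly continental study
climate: a sinusoidal seasonal cycle anchored at January/July means of
−32.3/17.8 °C with AR(1) monthly noise, and gamma-distributed monthly
precipitation around seasonal means that sum to 303 mm yr⁻¹ (January
15 mm, July 56 mm, June–August 47% of the annual total). What it does
*not* emulate: interannual regime shifts, precipitation–temperature
cross-correlation, or millennial transient trends (a linear trend term is
available). `generate_synthetic_landscape()` produces a spectrally
synthesized fractal elevation model, slope from central differences, a
single-flow-direction TWI rescaled to the observed range [7.1, 15.5], and
a lowest-lying water fraction. Any monotone TWI construction suffices
here, because only the rescaled range and ordering enter the fire engine.
Passing tests on these generators therefore demonstrate internal
consistency of the mechanisms under realistic stationary conditions, not
agreement with any specific transient climate reconstruction.

## Scenarios, outputs, analysis

The scenario suite holds 23 runs: with-fire and without-fire references,
six one-at-a-time sensitivity runs (monthly temperature, precipitation,
and fire mortality at ±5%), and the 15 fixed combinations of fire return
interval (10, 50, 100, 200, 300 yr) by fire intensity (0.1, 0.5, 1.0), in
which every fire affects the whole area at exactly the labeled intensity.
Annual output records stem count (trees ≥ 130 cm, total and per species),
seedlings (0–40 cm), mean height of trees > 200 cm, the
evergreen:deciduous ratio (missing when no deciduous tree is alive), mean
litter and active-layer depth, the annual rating, and burned cells;
spatial snapshots per 90 m cell are written every 100 years.

Post-fire responses are summarized by superposed epoch analysis: windows
of 10 pre-fire to 30 post-fire years around every fire, summarized by the
across-event median and quartile band. Windows truncated by the series
edges are dropped (and counted); overlapping windows are kept, since
superposition tolerates overlap. The pre-fire baseline for recovery is the
mean of the SEA median over relative years −10…−1 (the published analysis
does not define its baseline; a window mean is the least-structured
choice), and recovery time is the first post-fire year at which the median
regains that baseline.

## Numerical and design choices

* Coordinates are continuous meters, origin at the south-west corner,
  half-open cells $[i\cdot res, (i+1)\cdot res)$; the fine grid tiles the
  coarse grid exactly.
* One master seed feeds independent named RNG substreams (ignition,
  placement, fire impacts, demography, litter disturbance), so toggling
  the fire module does not perturb demographic draws; runs are
  bit-reproducible by seed.
* The fire step precedes demography within a year, so post-fire
  establishment can respond in the same season — consistent with recovery
  beginning a few years post-fire.
* Temperature localization is additive, precipitation multiplicative
  (standard bias-correction convention); only monthly means are matched,
  not variances. Ground seed pools are stored as expected counts with
  Poisson germination draws; exact per-seed binomials at 245k cells would
  change nothing at the simulated rates.
* Scaled-down problem sizes are used throughout the tests and the
  acceptance script as the package's standard desk-scale configuration: a
  99 × 99 m area (3 × 3 coarse cells at 33 m; 495² ≈ 245k fine cells),
  700-year scenario runs in the tests and a 2,500-year run (500-year
  spin-up) in the acceptance script. The full 990 × 990 m, multi-millennia
  configuration is supported but is a long run.

## Known limitations

No active fire spread, overwintering fires, multiple ignitions per year,
fuel-load dynamics, or human suppression; no multilayer permafrost
physics (the Stefan law is a single-layer proxy); no trait variation or
inheritance; isotropic dispersal only. The fire-weather coefficients
shipped as defaults are a documented stand-in parameterization — the
published fit's coefficients are not available — so absolute rating values
are only meaningful relative to the thresholds and after calibration of
the annual scale.
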