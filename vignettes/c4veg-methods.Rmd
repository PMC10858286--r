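---
title: "Mapping C4 vegetation from photosynthetic optimality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping C4 vegetation from photosynthetic optimality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`c4veg` estimates where C4 vegetation (natural grasses and crops) occurs, how
much of the land surface it occupies, why that has changed, and how much of
global photosynthesis it performs. This vignette is the package's own account
of the science: the models, their assumptions, the parameters that matter,
what the synthetic world does and does not emulate, and the numerical and
design choices that were genuinely open.

## 1. The leaf optimality model

### Biochemistry

C3 net assimilation follows the Farquhar–von Caemmerer–Berry scheme: the
gross rate is the minimum of the Rubisco-limited and RuBP-regeneration-limited
rates,

$$A_{C3} = \min\!\left(
  V_{cmax}\frac{c_i - \Gamma^*}{c_i + K_c(1 + O/K_o)},\;
  \frac{J}{4}\frac{c_i - \Gamma^*}{c_i + 2\Gamma^*}\right) - R_d,$$

with $J$ from the usual non-rectangular hyperbola
($\theta J^2 - (\alpha I + J_{max})J + \alpha I J_{max} = 0$, $\theta = 0.7$,
$\alpha = 0.3$). Kinetic constants at 25 °C ($K_c = 404.9$ µmol mol⁻¹,
$K_o = 278.4$ mmol mol⁻¹, $\Gamma^* = 42.75$ µmol mol⁻¹) follow standard
in-vivo values with Arrhenius temperature responses; $V_{cmax}$ and $J_{max}$
use a peaked Arrhenius form ($H_d = 200$ kJ mol⁻¹, $\Delta S = 640$
J mol⁻¹ K⁻¹).

C4 assimilation follows the Collatz-type three-limitation scheme,

$$A_{C4} = \min\!\left(V_{cmax}(T),\; \alpha_4 I,\; k_p(T)\, c_i\right) - R_d,$$

where $k_p$ is the PEP-carboxylase initial slope. The CO2-concentrating
mechanism appears as the steep $k_p c_i$ branch: at ambient $c_i$ the C4 rate
is nearly CO2-saturated, which is why C4 plants gain little from rising CO2
while C3 plants gain a lot. C4 kinetics use $Q_{10} = 2$ with logistic low-
and high-temperature inhibition (half-points 13 °C and 38 °C).

The exact parameter set behind the original model lives in supplementary
material that is not redistributable here, so the defaults in
`photo_params()` are standard literature values and are explicitly
provisional; every constant sits in one place and can be overridden.

Pathway-specific capacities derive from leaf nitrogen through a linear map
(`nitrogen_to_capacity()`), with the optimal ratios $J_{max}/V_{cmax} = 2.1$
(C3) and $5.0$ (C4). The C4 slope (10 µmol g⁻¹ N vs 25 for C3) encodes the
lower Rubisco load of C4 leaves; default capacities ($V_{cmax,25}$ 50 / 20
µmol m⁻² s⁻¹ for C3 / C4 at ~2 g N m⁻²) were chosen once so that the modeled
AC4/AC3 field spans roughly 0.5–2.5 over warm open land, the observed range
of the advantage ratio. Since C4 grasses in forests and shrublands live in
the understory, closed-canopy cells attenuate light by Beer's law,
$I_u = I_0 e^{-k L}$, with $k = 0.5$.

### The optimization

Each pathway chooses stomatal resistance $r_s$ (equivalently conductance
$g = 1/r_s$) and a fine-root allocation fraction $f$ to maximize

$$G = A(g) - \lambda E - c_{root} f, \qquad E = 1.6\, g\, D / P_{atm},$$

subject to the soil–plant–air water balance: supply
$k_{plant}\, f\, (\psi_{soil} - \psi_{min})$ must meet transpiration demand
$E$. The assimilation–diffusion coupling $A = g(c_a - c_i)$ is solved
analytically per limitation branch (each branch yields a quadratic or linear
equation in $c_i$; the coupled rate is the minimum of the branch solutions,
since all demand curves are nondecreasing in $c_i$). Defaults:
$\lambda = 400$ µmol CO2 per mol H2O, $c_{root} = 10$ µmol m⁻² s⁻¹,
$k_{plant} = 0.004$ mol m⁻² s⁻¹ MPa⁻¹, $\psi_{min} = -3$ MPa. The form of
$G$ is the package's own concretization of "maximize carbon gain against
water loss"; $\lambda$ and $c_{root}$ are ordinary configuration parameters.

Because $A$ does not depend on $f$, the optimal $f$ for any $g$ is the
smallest feasible one, $f^*(g) = E(g)/(k_{plant}\Delta\psi)$; substituting it
reduces the problem to a one-dimensional concave-ish search over $g$, solved
by a 16-point log-spaced coarse grid (multistart) plus golden-section
refinement (tolerance $10^{-7}$), with a deterministic fallback to the best
coarse-grid point. The tests verify equivalence with an exhaustive, iterated
200×200 grid search over $(r_s, f)$ to $10^{-4}$ relative on randomized
environments. Soil at the $-3$ MPa floor under nonzero VPD admits no
transpiration: the solver returns the closed-stomata solution (zero
assimilation and gain, flagged `water_supply`) rather than erroring.

Emergent directions — the ones that make the map — are properties, not
inputs: the AC4/AC3 ratio rises with temperature (10–35 °C), falls with CO2,
rises with aridity, and collapses toward 1 under deep shade.

## 2. From occurrences to coverage observations

Trait-database occurrence records are filtered to herbaceous non-crop
species (woody first, then the four major C4 crops — maize, sugarcane,
millet, sorghum — so a doubly flagged record counts once, under woody), then
aggregated to 10°×10° cells with case-insensitive species deduplication.
Cells with fewer than 50 species are dropped: below that, a richness
percentage is mostly sampling noise. Cells are half-open intervals anchored
at −90°/−180°; boundary records belong to the lower cell.

Species richness (% of species that are C4) is not areal cover. The
conversion factor comes from plot-level paired observations: pairs are
grouped by rounded richness (the smallest grouping consistent with
"per-richness mean and sd"), and 1000 bootstrap replicates each draw one
cover value per group from Normal(mean, sd) and fit a through-origin
least-squares line — the zero intercept encodes that C4 cover must vanish
where no C4 species occur. The factor is the replicate mean, its uncertainty
their sd. Converted coverage is capped at 100%.

## 3. The ratio–coverage curve

Observed coverage rises with the modeled AC4/AC3 and plateaus near 100%. The
functional family is not dictated by theory; the default is the scaled
logistic $100/(1+e^{-(a + b\,\rho)})$ — two parameters, monotone, the right
plateau — with Gompertz as a configurable alternative. Fitting is nonlinear
least squares from a linearized start with multistart, falling back to
direct Nelder–Mead least squares when residuals are (near-)zero, where `nls`
fails by construction. The 95% band is a 1000-replicate residual bootstrap
(percentile method, fixed seed). Model output is aggregated to the
observations' scales (1°, 10°) by block means; the fitted relationship is
treated as scale-independent and time-invariant, and TRY- and DG-style
sources are pooled unweighted. Per-source refits are supported as a
diagnostic, not asserted to agree.

The crossover-temperature baseline (month favors C4 iff daytime air
temperature > 22 °C and precipitation ≥ 25 mm, strict and inclusive
respectively) is retained for comparison only; unlike the curve, it assigns
the whole pixel's grassland to C4 wherever the rule fires. Its
CO2-dependence is out of scope.

## 4. Area abundance, change, attribution

Coverage (% of grassland) becomes area abundance (% of land surface) by
multiplying with the grassland fraction — the mean of two remote-sensing
products, whose per-cell uncertainty is the sd of 1000 draws picking either
product at random (independently per cell, the per-pixel reading of the
procedure; the sd converges to half the inter-product disagreement). Crop
abundance is the crop fraction itself with a flat 10% relative uncertainty
(the documented between-product spread of cropland datasets). How
uncertainties combine is not specified upstream, so independent-error
quadrature on relative sds is used throughout; half-widths of the curve's
95% band serve as the coverage uncertainty.

Global summaries weight cells by cos(latitude) (absolute areas use spherical
cell areas, R = 6371 km) over a configurable land mask; the default mask is
the growing-season (non-frozen) domain, and the config exposes it because
the printed denominators are ambiguous between "non-frozen" and "vegetated".
Change compares 2001–2005 and 2015–2019 period means (simple averages of
annual grids). Synergy classes (++, −−, +−, −+) are computed only over cells
where both grass and crop components occur; zero-change cells are excluded
from the denominator so shares sum to one.

Attribution is by scenario replacement: rerun the baseline-year pipeline
with exactly one driver (CO2, temperature, VPD, soil moisture) replaced by
its target-year field, holding the grassland fraction fixed so the signal is
purely climatic. Single-driver deltas are reported next to the full change
with an explicit interaction residual — never forced to add up.

## 5. The emergent constraint

Across a vegetation-model ensemble, the C4 share of global GPP regresses
tightly on the C4 share of vegetated area even though both spread widely
across models; that across-model line, evaluated at the observation-
constrained area, yields the GPP share. The fit is OLS with the slope's
standard error from bootstrapping models with replacement (degenerate
resamples redrawn). Application uses the full fitted line (slope +
intercept): the ensemble regressions are ordinary linear fits with free
intercepts, so dropping the intercept would bias the prediction; slope-only
scaling remains available as a config switch. Applied uncertainty jointly
resamples the area (Normal with its sd) and the coefficients (from the
bootstrap replicates). Annual series fit per year and component; grass and
crop applications add, with standard errors in quadrature.

## 6. The synthetic world

Every pipeline input has a generated stand-in with recorded ground truth, so
the whole chain is testable offline. Stated once:

* 5° global grid (36×72), years 2001–2019 (0.5° is supported but slow).
* True ratio→coverage curve: logistic with $a = -7.9$, $b = 5.0$ — the
  two-point solution of the anchors "5.2% coverage at ratio 1" and "~99% at
  ratio 2.5".
* True conversion slope 1.51 (% cover per % richness), with 15% cover
  within-group sd across 15 richness groups × 4 control plots — plot-scale
  cover variability at a realistic survey size.
* CO2 370 ppm in 2001, +2 ppm yr⁻¹ (exact, noise-free); warming
  0.03 °C yr⁻¹; VPD +0.002 kPa yr⁻¹; mild soil drying.
* Temperature follows a growing-season gradient (28 °C at the equator to
  ~12 °C at the 65° mask edge — flat near the equator because these are
  growing-season, not annual, means), a subtropical dryness belt shapes VPD
  and soil moisture, and tropical forest cells are closed-canopy with
  overstory LAI 4.
* Grassland-fraction products straddle their truth by a 0.06 disagreement;
  the crop pattern's global mean expands 2.6% → 3.0% of land, linearly.
* Ensemble: 11 members (7 for crops), areas spread 7–23% (grass) with GPP on
  the true line (slope 1.11→1.10 grass, 1.16→1.15 crop, zero intercept) plus
  scatter.

Observation error on coverage acts on the logit scale (mid-scale sd 5%),
which keeps observations in (0, 100) and median-unbiased for the true curve
— additive noise clipped at the bounds would systematically contradict the
generator's own truth near the plateau. Fraction noise is clipped Gaussian,
as fractions must live in [0, 1].

What the generator does **not** emulate: realistic spatial covariance
beyond smooth low-order fields, seasonality (drivers are growing-season
means), fire, land-use transitions between grass and crop, and the
geographic clustering of real observations. A green closed-loop test
therefore establishes that the estimators recover the stated world's truths
at realistic noise — not that the real-data headline numbers are reproduced;
those require the external global datasets.

## 7. Tolerances and their derivation

* Solver vs. exhaustive grid oracle: $10^{-4}$ relative on the objective.
* Conversion factor: recovered within 2 bootstrap sd; 95% interval covers
  truth in ≥ 90 of 100 repeats.
* Curve (isolated fit): true parameters inside the 95% residual-bootstrap
  band.
* Curve (full closed loop): fitted coverage within 6 percentage points of
  the true curve over the observed ratio range. Parameter-band coverage is
  the wrong closed-loop criterion: the conversion factor's sampling error
  (sd ≈ 0.07–0.15 at the stated plot count) rescales every TRY-derived
  coverage by a shared factor that a residual bootstrap cannot represent,
  sliding $(a, b)$ along their ridge while the curve itself barely moves.
  Two sd of that shared error is ≤ 5 points mid-scale; ~1 point of fit noise
  gives the stated 6.
* Constraint: slope within 2 bootstrap se; noise-free generators recover
  their lines exactly.
* Noise-free end-to-end: global grass abundance within 0.5 points absolute
  of the synthetic truth.

## 8. Numerical choices and degenerate inputs

Grids are cell-centered, latitude descending, longitude in [−180, 180);
every loader validates geometry and mismatch errors name the offending
field. Raster interchange is a plain-text CSV format (17 significant
digits, bitwise round-trip) because no binary raster library is assumed.
All stochastic stages take explicit seeds derived deterministically from the
master seed; identical configurations are bit-identical. Fully masked
inputs yield fully masked outputs; empty masks error; ratios where either
pathway assimilates nothing are masked rather than infinite or negative;
ratios above 10 are flagged suspect but still evaluated. The package's
functions (plus `scripts/acceptance.R`) are the command-line surface; no
separate shell tool is shipped.

## 9. Known limitations

Annual growing-season means preclude seasonal C3/C4 switching (the monthly
crossover baseline exists partly for that comparison); no canopy-scale GPP
is simulated — the GPP share comes from the emergent constraint, not from
integrating the leaf model; phylogenetic structure, fire, and nitrogen
deposition are not represented (leaf nitrogen input captures part of the
latter); kinetic defaults are provisional pending the original
parameterization; and the real-data headline quantities are reachable only
with the external climate, trait, land-cover and model-ensemble datasets
this package consumes but does not ship.
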