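---
title: "Methods: from leaf biochemistry to yield sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from leaf biochemistry to yield sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soycansim)
```

This vignette is the package's own account of its science: the models,
the constants and why they hold their default values, what the
synthetic weather does and does not emulate, and the numerical choices
that a user extending the package should know about.

## The leaf model

Net assimilation is the classical three-way minimum
`An = min(Ac, Aj, Ap) - Rd`, with ties broken in the order
Rubisco < RuBP < TPU. The candidate rates and the coupled Ball-Berry
solve are described in `?assimilation_at_ci` and `?solve_coupled`. Two
accounting identities are enforced and tested: `Vc - Rp - Rd = An`
above the compensation point, and `Rp/Vc = gamma_star/Ci`, which makes
the ratio of a photorespiration increase to a carboxylation increase
equal to `100 * gamma_star / Ci` percent whenever both scenarios are
evaluated at the same `Ci`.

### Parameter choices

The source crop model family publishes its capacities
(`vcmax25 = 110`, `jmax25 = 195` umol m-2 s-1 for soybean) but not its
kinetic constants, light-response curvature or temperature functions.
We therefore adopt the community-standard C3 set, recorded in
`inst/extdata/leaf_params.yaml` (one file, fully re-parameterizable):

* `kc25 = 404.9` umol mol-1, `ko25 = 278.4` mmol mol-1,
  `gamma_star25 = 42.75` umol mol-1, `o2 = 210` mmol mol-1 — the
  standard 25 degC Rubisco kinetics;
* Arrhenius temperature scaling with the usual activation energies
  (e.g. 65.33 kJ mol-1 for Vcmax, 79.43 for Kc); at 25 degC every
  parameter equals its reference value exactly;
* light response: non-rectangular hyperbola with `theta = 0.7` and
  PSII-effective light `I2 = q * 0.85 * (1 - 0.15) / 2 = 0.361 q`
  (absorptance times spectral correction over two photosystems);
* `tpu25 = 23` umol m-2 s-1, high enough that TPU never limits below
  `Ci` of ~1500 at any light level used here — deliberately, since TPU
  limitation is rare at current and near-future CO2;
* Ball-Berry `slope = 8`, `intercept = 0.01` mol m-2 s-1. The slope
  sits in the soybean literature range (roughly 8-11); the lower end
  keeps midday `Ci/Ca` near 0.72, which places the leaf close to the
  Ac/Aj crossover at 400 ppm so that a realistic minority share of
  daylight hours is Rubisco-limited;
* `rd25 = 1.2` umol m-2 s-1 (~1.1% of Vcmax25), the measured soybean
  leaf value. Dark respiration co-scales with any Vcmax scaling
  factor, so a scenario that raises carboxylation capacity also pays
  its respiratory cost. An earlier build used 1.5% of Vcmax; once
  maintenance respiration of the non-leaf biomass was made explicit
  (below) that choice double-counted respiration and visibly distorted
  the CO2 dependence of the yield response, so the measured leaf value
  is used instead.

With this set, the Ac/Aj transition at `Q = 1500` lands at ~313 ppm
(control) and ~432 ppm (Jmax x1.2), and at `Q = 800` at ~232/~294 ppm;
the mean leaf-level An gain from a 20% increase of both capacities over
`Ci` in [400, 600] is ~16% at high light and ~12% at moderate light.
These are the quantities `scripts/acceptance.R` recomputes.

## The canopy

Ten layers, sunlit/shaded, spherical leaf-angle distribution
(`k_beam = 0.5 / cos(zenith)`, beam dropped when the sun is within ~3
degrees of the horizon), `k_diffuse = 0.7`, scattering 0.2. The diffuse
fraction of incident light follows a clearness-index rule that is
quadratic in (1 - clearness): 0.23 under clear sky, 1 under overcast.
Photosynthetic capacity (and hence leaf Rd) decays with cumulative leaf
area as `exp(-k_nitrogen * L)` with `k_nitrogen = 0.10` per unit LAI —
the standard canopy nitrogen profile. Without it a uniform canopy
respires implausibly hard at depth (double-digit umol m-2 s-1 of
nocturnal canopy Rd at LAI 8) and the seasonal LAI response to capacity
scaling even turns negative; 0.10 sits in the low-middle of reported
values and leaves the biomass cost of extra leaf area present but not
overwhelming.

Within-canopy air temperature and humidity gradients are ignored
(ambient values at all layers), and air temperature is used as leaf
temperature. Evapotranspiration is Penman-Monteith with the LAI-weighted
sum of layer stomatal conductances and a log-profile aerodynamic
conductance for a 1 m canopy; WUE = An/E is undefined (NA) for hours
without evaporative flux, and daily WUE averages use daylight hours
with E above a small threshold only, because the ratio degenerates as
E approaches zero in humid dawn hours.

## The crop

Development is thermal time above 10 degC from sowing (DOY 152):
reproductive onset at 750 degC day, senescence onset at 1000, maturity
at 1600 — an Illinois-like calendar with reproductive onset near DOY
205-210 and maturity in late September. Carbon conversion uses 30 g
carbohydrate per mol CO2 and a growth efficiency of 0.7. Positive net
carbohydrate first refills a labile pool up to 15% of green leaf
biomass (the diel starch cycle); night deficits draw on that pool
before any structural mass is touched. Without this buffer, night
respiration eats structural leaf directly while daytime gains reach the
leaf only through the partition fractions, and raising Rd along with
Vcmax shrinks the canopy — an artefact, not physiology.

Maintenance respiration is charged on stem, root and pod at
0.008/0.005/0.004 g per g per day (25 degC, Q10 = 2); leaf maintenance
is already carried by the canopy's FvCB dark respiration. This is a
deliberate departure from folding all maintenance into leaf Rd: with no
biomass-proportional cost, a season that builds a larger canopy carries
it through pod filling for free, and the negative LAI-gain/pod-gain
relationship across climate years — a central feature of the analysis —
cannot emerge. The coefficients are standard crop-model values.

Partitioning uses logistic weights of development stage, normalized to
sum to one, with the pod weight gated to zero before reproductive
onset. The defaults (leaf 0.42 / stem 0.40 / root 0.22 schedules, pod
logistic centred at stage 0.58) were chosen so that a typical synthetic
year at 400 ppm yields control pod ~5-7 Mg/ha, shoot ~9-10 Mg/ha and
peak LAI ~6-8 — the observable ranges for productive Midwest soybean —
without claiming the source model's cultivar calibration. Carbon
conservation is exact at every step: pool deltas plus senescence equal
`0.7 * assimilate - maintenance`.

### Numerical scheme

The season loop refreshes the canopy light environment once per day
with the start-of-day LAI and solves all 24 hours of that day as one
vectorized batch; growth, development and the labile pool still step
hourly. LAI changes by at most a few percent per day, so the error of
freezing it within a day is far below the layer-discretization error
(itself under 2% against a 100-layer refinement, which is tested). A
full season solves in a fraction of a second, which is what makes
200-member bootstrap ensembles and factorial scaling grids practical on
one CPU; the test suite uses 2-4 synthetic years, a 5x5x2 grid and a
200-member ensemble for exactly that reason.

The coupled leaf solver is a damped fixed point on `Ci` (start
`0.7 Ca`, damping 0.5, relative tolerance 1e-8, cap 200 iterations)
with a per-element bisection fallback; it is deterministic and is
cross-checked in the tests against an independent bisection oracle.

## Synthetic weather

`generate_archive()` emulates the statistical structure that the
bootstrap and PRCC stages rely on: solar-geometry diurnal PPFD under an
AR(1) day-level cloudiness factor; temperature as seasonal sinusoid
plus AR(1) daily anomalies and a diurnal cycle lagging radiation by ~3
hours; within-day humidity anti-correlated with temperature; two-state
wet/dry precipitation occurrence with wet days cloudier and more humid;
lognormal wind; and year-level anomalies for interannual variability.
Nights are exactly dark; years are 365 days (the bootstrap documents
the leap policy: day 366 is drawn only from leap years and dropped when
none exist).

What it does *not* emulate: weather fronts and multi-day synoptic
persistence beyond AR(1), heat waves co-occurring with drought, hail or
frost, and any trend or future-climate structure. Consequently, tests
that pass on synthetic weather demonstrate that the pipeline's
machinery and couplings behave correctly, not that the specific
Bondville-decade numbers are reproduced; feeding the real station CSV
through `read_weather_csv()` is supported but intentionally outside the
test suite.

The bootstrap samples, for each day of year, that day's complete
24-hour record for all variables from one uniformly drawn archive year
(with replacement across days, independently per day). Child seeds for
ensemble replicates expand deterministically from one master seed by a
counter scheme, so any replicate can be reproduced in isolation.

## Sensitivity machinery

Relative changes use the `100 * (VxJx - CTL) / |CTL|` convention; the
absolute-value denominator is adopted literally, which preserves the
numerator's sign for negative controls (all controls in practice are
positive). Surfaces are interpolated with a tensor product of 1-D Akima
local splines, implemented in the package (~60 lines): local,
overshoot-resistant, exact at the nodes and for planar data, with a
natural-spline tensor fallback behind `method = "spline"`. Gradients
are symmetric central differences with `h = 0.01`; paths use
`alpha = 0.001` by default. The path routine exposes an
ascend/descend switch because the relevant question ("where do gains
grow fastest?") is an ascent even though the update rule is
conventionally written with a minus sign.

PRCC is implemented internally via the regression-residual definition
(rank-transform everything; correlate the residuals of the focal driver
and of the response after regressing both on the other drivers), with
p-values from the t transform on `n - (k - 1) - 2` degrees of freedom,
reported raw (no multiplicity adjustment). The test suite checks it
against an independent precision-matrix formulation to 1e-10.
Per-phase driver summaries use each replicate's *own* simulated phase
windows, not fixed calendar dates; precipitation enters as a phase
total (the agronomic quantity), the other drivers as means — both
switchable.

## Known limitations

* The CO2 attenuation of the pod-yield gain (smaller relative gains at
  800 than at 400 ppm) holds robustly for assimilation, shoot and LAI,
  and for pod at moderate (+25%) capacity scaling; at the extreme
  +50%/+50% corner of the design the pod contrast on synthetic weather
  is flat to slightly inverted. The balance there is set by opposing
  respiration and LAI-feedback terms and is sensitive to the crop
  configuration.
* WUE levels (~9 umol mmol-1 daylight mean) are on the high side of
  field estimates; the simplified net-radiation and aerodynamic
  treatment is the likely cause. WUE enters no quantitative claim.
* Soil water is non-limiting by design (precipitation is carried
  through I/O and PRCC but does not modulate growth), there is no
  nitrogen economy, no mesophyll conductance, and no leaf energy
  balance.
* The crop configuration is a defensible generic Midwest soybean, not
  a cultivar calibration; absolute biomass numbers should be read as
  regime-level, not predictive.
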