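# soycansim

Mechanistic soybean canopy-photosynthesis and growth simulation, with
the sensitivity machinery to ask a deceptively simple question: if crop
engineering raises the two headline photosynthetic capacities — the
maximum Rubisco carboxylation rate (V<sub>cmax</sub>) and the maximum
electron transport rate (J<sub>max</sub>) — how much of that gain
survives the trip from a leaf to a season's pod yield under real,
variable weather and rising CO₂?

The package is aimed at crop ecophysiologists and modellers who want a
self-contained, testable pipeline: every stage runs on synthetic weather
with realistic statistical structure, so no station downloads are
needed, and a real hourly weather CSV can be dropped in at any point.

## The model

**Leaf.** Steady-state C3 gas exchange follows the
Farquhar–von Caemmerer–Berry (FvCB) scheme: net assimilation is

A<sub>n</sub> = min(A<sub>c</sub>, A<sub>j</sub>, A<sub>p</sub>) − R<sub>d</sub>

with the Rubisco-limited rate
A<sub>c</sub> = V<sub>cmax</sub>(C<sub>i</sub> − Γ\*)/(C<sub>i</sub> + K<sub>c</sub>(1 + O/K<sub>o</sub>)),
the RuBP-regeneration-limited rate
A<sub>j</sub> = J(C<sub>i</sub> − Γ\*)/(4C<sub>i</sub> + 8Γ\*) where J is
the smaller root of the non-rectangular hyperbola
θJ² − (I₂ + J<sub>max</sub>)J + I₂J<sub>max</sub> = 0, and a
triose-phosphate-utilization cap A<sub>p</sub> = 3·TPU. Stomata follow
Ball–Berry, g<sub>s</sub> = m·A<sub>n</sub>·RH/C<sub>a</sub> + b,
coupled to the supply constraint
C<sub>i</sub> = C<sub>a</sub> − 1.6·A<sub>n</sub>/g<sub>s</sub> and
solved as a damped fixed point. Photorespiratory release obeys
R<sub>p</sub>/V<sub>c</sub> = Γ\*/C<sub>i</sub>.

**Canopy.** A 10-layer sunlit/shaded scheme with a spherical leaf-angle
distribution (k<sub>beam</sub> = 0.5/cos z), Beer-law attenuation of
beam and diffuse streams, an exponential nitrogen/capacity profile with
depth, Penman–Monteith evapotranspiration from the bulk canopy
conductance, and WUE = A<sub>n</sub>/E.

**Crop.** Hourly carbon gain drives photothermal development
(thermal time above 10 °C), logistic partitioning into leaf, stem, root
and pod pools, a labile carbohydrate pool that buffers night
respiration, Q10-scaled maintenance respiration on the non-leaf pools,
and leaf senescence. LAI feeds back on light interception daily.

**Sensitivity machinery.** Factorial scaling grids over
(V<sub>cmax</sub>, J<sub>max</sub>) at several CO₂ levels with
relative changes measured against the paired control
(Δ = 100·(VxJx − CTL)/|CTL|); Akima-spline response-surface
interpolation with central-difference gradients and steepest-path
tracing (X<sub>n+1</sub> = X<sub>n</sub> ± α∇f); a day-block bootstrap
that builds synthetic years by sampling whole 24-hour records per day of
year; and partial rank correlation (PRCC) attribution of pod-yield
gains to the climate drivers of the vegetative and reproductive phases.

## A worked example

```r
library(soycansim)

p <- leaf_params()          # Vcmax25 = 110, Jmax25 = 195 umol m-2 s-1
solve_coupled(leaf_env(q = 1500, t_leaf = 25, rh = 0.7, ca = 400), p)
#>        ci     an    gs     vc    rp  limiting
#>   288.783 25.888 0.372 31.795 4.707   rubisco

find_transition_ci(1500, 25, p)$ci_star
#> [1] 312.6748    # Ci where Ac = Aj; above it RuBP regeneration limits

arch <- generate_archive(2, seed = 42)       # synthetic Illinois-like years
ctl  <- simulate_season(arch[arch$year == 2001, ], co2 = 400)
ctl
#> <season_result> co2 400 ppm, scales (1.00, 1.00)
#>   pod 5.71  shoot 9.08 Mg/ha; max LAI 6.08
#>   An daily-max mean 22.52, daily-mean mean 7.85 umol m-2 s-1; WUE 9.13 umol mmol-1
#>   phases: vegetative DOY 152-199, reproductive 200-278

v20 <- simulate_season(arch[arch$year == 2001, ], co2 = 400,
                       scale_v = 1.2, scale_j = 1.2)
relative_change(v20$summary$pod, ctl$summary$pod)
#> [1] 4.21        # a 20% capacity increase buys ~4% pod yield
```

The numbers tell the story at each scale: the leaf operates near the
A<sub>c</sub>/A<sub>j</sub> crossover at current CO₂ (C<sub>i</sub> ≈ 289
vs a transition at ≈ 313 ppm), a season integrates to ~5.7 Mg/ha of pod,
and a 20% boost of both capacities survives as only a ~4% pod gain —
attenuated by canopy light interception, respiration and carbon
allocation.

Larger experiments follow the same pattern: `run_grid()` sweeps the
scaling design and feeds `interpolate_surface()`/`steepest_path()`;
`run_bootstrap_ensemble()` plus `prcc_by_phase()` attribute the spread
of pod gains across 200+ resampled climate years to per-phase drivers.
A thin command-line wrapper for weather synthesis, A-Ci curves and
season runs lives in `inst/cli/soycansim.R`.

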