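---
title: "Inverse modeling of soil organic carbon pools with socfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse modeling of soil organic carbon pools with socfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socfit)
```

## The model and its assumptions

`socfit` simulates the carbon content of eight coupled pools at a monthly
time step: surface and soil structural and metabolic litter, a surface
microbial pool, and active, slow and passive soil organic matter (SOM).
Decomposition is first-order in each pool's mass, and every decomposition
event splits its carbon between destination pools and respired CO2
according to fixed flow fractions, so total carbon is conserved exactly:
the monthly change in system carbon equals litter inputs minus CO2. The
observable fitted to data is the sum of the active, slow and passive
pools, matching what a 0-20 cm SOC stock measurement sees; litter standing
stock is transient and excluded.

Key structural assumptions:

* **Exogenous climate.** The abiotic rate factor `defac` (a combined
  temperature-moisture multiplier, 0-1 in practice) is an input series,
  not modeled. Plant growth and nutrient cycling are likewise outside the
  model: carbon inputs come either from observed yields via agronomic
  indices or from an external model's output.
* **Rate modifiers are multiplicative.** The monthly rate is
  `k0/12 * defac * texture * lignin * mgmteff`, with texture slowing the
  active pool (`1 - 0.75*(clay+silt)`) and lignin slowing structural
  litter (`exp(-3 * lignin fraction)`).
* **Management acts on decay of the active and slow pools only**, through
  `mgmteff = clteff * ferteff * omeff`. Passive SOM and litter decay are
  unaffected.
* **Pool topology.** Structural litter routes its lignin share to the
  slow pool and the remainder through the microbial/active chain;
  metabolic litter feeds the surface microbial pool (surface) or the
  active pool (soil); the surface microbial pool feeds the slow pool;
  active, slow and passive exchange with texture-dependent fractions.
  Whether surface microbes should instead feed the active pool is not
  settled in the model family's descriptions; we adopt the
  surface-microbe-to-slow route and expose every flow fraction in
  `century_kinetics()` so the choice is overridable.

The default maximum decay coefficients (yr⁻¹: surface structural 3.9,
soil structural 4.9, surface metabolic 14.8, soil metabolic 18.5, surface
microbe 6.0, active 7.3, slow 0.2, passive 0.0045) follow the published
CENTURY agroecosystem parameterization. They are configuration, not
constants, precisely because variant tables exist.

## Integration

Within a month all rate coefficients are frozen at their month-start
values, litter inputs are credited with the step (they are not decayed in
their arrival month), and the linear system is advanced either by
explicit Euler or by the Crank-Nicolson average-of-endpoints scheme,

    (I - M/2) C(m+1) = (I + M/2) C(m) + u.

Crank-Nicolson is the default: it is second-order accurate (halving the
step quarters the error against the analytic exponential) and cannot
produce negative masses for per-month rates below 2, whereas Euler fails
at rates above 1 — which the soil metabolic pool can reach under high
`defac`. A step that would still drive a pool negative raises an error
naming the pool rather than clamping, so parameter pathologies surface
during fitting instead of being silently absorbed.

## Carbon inputs

Yield-to-residue conversion uses harvest index, root-to-shoot ratio, the
fraction of roots in 0-20 cm, grain moisture θ and residue carbon
concentrations, with crop defaults for corn, soybean and winter wheat
shipped in `crop_indices()`. Two readings of the moisture term are
possible in this model family's documentation; we divide by 100
(`(100-θ)/100`, a dry-matter fraction), since the alternative inflates
inputs a hundredfold and breaks dimensional consistency with Mg-scale
stocks. The tillage mixing fraction sends 95% (CT) or 5% (NT) of
aboveground residue into the soil; the remainder accumulates in surface
litter pools. Amendments are assumed fully incorporated regardless of
tillage (the sources do not state a mixing fraction for manure) and split
60/40 between metabolic and structural soil litter — a configurable
default, since manure partitioning is likewise unstated. Annual inputs
are deposited as a single harvest-month pulse by default
(`annual_to_monthly_inputs()` supports arbitrary schedules).

## Management effects

Fertilization and amendment effects are class-based (N: low ≤100, mid
100-200, high ≥200 kg N ha⁻¹ yr⁻¹; OM: mid ≤10, high >10 t DM ha⁻¹
yr⁻¹) and parameterized on the log scale so exponentiated effects are
positive and an inactive practice contributes exactly 1. Two boundary
conventions had to be fixed: 100 belongs to low and 200 to high (matching
the printed class definitions), and an OM rate of exactly 10 — which the
printed definitions assign to both classes — goes to mid. Effects apply
for all 12 months of the calendar application year with no carry-over;
whether the original fits used a calendar year or 12 months from the
application month is not documented, and the difference is immaterial for
the annually repeated treatments the design targets. The tillage effect
is fixed rather than fitted (5.5 in the tillage month, or its annualized
equivalent 1.4 over the following year — note `(5.5+11)/12 = 1.375`);
overlapping annualized windows take the maximum rather than compounding.

## The Michaelis-Menten variant

As an alternative to a fitted fertilization effect, decay of the active
and slow pools can be made substrate-dependent:
`k* = k0/12 * defac * texture * clteff * vmax*C_MR/(km + C_MR)`, where
`C_MR` is the soil metabolic litter mass — a proxy for microbially
available fresh carbon. We deliberately exclude any additional factor of
the decaying pool's own mass from the rate coefficient: that would make
the flux quadratic in pool size and dimensionally inconsistent with the
first-order flux definition. `C_MR` is evaluated at month start (lagged),
which keeps each monthly step linear and the Crank-Nicolson solve exact.
The tillage series is retained in this mode; fertilization and amendment
multipliers are removed, since the substrate dependence is meant to
replace their input-mediated pathway. `vmax` and `km` are fitted on the
log scale jointly with the initial-fraction parameters.

## Inverse fitting

The estimated parameters are the initial slow-pool fraction `f_S(0)` (one
per site, or per treatment where initial SOC observations differ within a
site), the log effects, and optionally `(vmax, km)`. The active fraction
is fixed at `f_A = 0.02` — it is small and re-equilibrates within a few
years regardless of its start — and the passive fraction is set by
difference. Residuals are observed minus predicted SOC pooled unweighted
across all sites and treatments (ordinary least squares); minimization
uses Levenberg-Marquardt damped least squares in the transformed space
(scaled logit for `f_S` with bounds [0.01, 0.95], identity for λ, log for
`vmax`/`km`), with convergence at a relative SSR change below 1e-10 and a
200-iteration cap. The covariance is `σ̂²(JᵀJ)⁻¹` with a
forward-difference Jacobian (relative step 1e-6), mapped to the natural
scale by the delta method; exponentiated effects are tested against 1 and
fractions against 0 with two-sided t tests on n-p degrees of freedom.
Goodness of fit is reported as the squared Pearson correlation between
observed and predicted SOC — the definition is stated here because
"R²" is ambiguous for nonlinear models, and observed-vs-modeled
correlation is what scatterplots against a 1:1 line display.

## Uncertainty

`draw_parameter_sets()` samples the multivariate normal in the
*transformed* space, so bound constraints survive back-transformation
without ad-hoc truncation distorting the covariance. Prediction intervals
are empirical percentiles (default 95%) of the forward-simulated draws at
each observation point; percentile intervals, not normal approximations,
because the back-transformed sampling distributions are skewed. A draw
whose simulation fails is resampled up to `max_resample` times and then
dropped; more than 10% failures aborts. The observation-perturbation
experiment (`perturb_observations()`, default CV 10%) replaces every SOC
observation and yield with a positive-truncated normal draw centred on
the recorded value; `synthetic_refit_interval()` refits and recomputes
intervals, which widen because the added measurement noise inflates the
residual variance and hence the parameter covariance.

## The synthetic-study generator

`synthetic_designs()`/`generate_study()` emulate the structure of US
long-term rain-fed corn experiments: 8-10 sites (configurable), 15-35 yr
records, corn-based rotations (CC/CS/CSW), N rates 0-336 kg N ha⁻¹ with
an unfertilized control at every site, amendments of 4.5-18 t DM ha⁻¹ at
two sites, CT and NT regimes, and sparse SOC sampling every 3-6 years
with 10% observation CV. True initial slow fractions are tied to prior
land use (grassland 0.6-0.8, recent cultivation 0.45-0.6, long
cultivation 0.3-0.45), reproducing the empirical pattern that sod-derived
sites start with larger labile stocks. Yields follow a saturating N
response `Y = Ymax(1 - exp(-(N + N0)/Nhalf))` with lognormal noise
(corn Ymax 11 Mg ha⁻¹, base supply N0 = 60, scale Nhalf = 80 kg N ha⁻¹ —
a realistic Midwest response); soybean is N-insensitive. `defac` is a
clamped sinusoid (mean 0.35, amplitude 0.25, white noise sd 0.03),
spanning the 0-0.6 monthly range typical of humid temperate cropland.

What the generator does *not* emulate: model-structure error (the fitted
model is the generating model, so recovery tests measure statistical
identifiability, not realism), spatially or temporally correlated
observation error, bulk-density and depth-support inconsistencies in SOC
time series, erosion and drainage history, and weather-driven yield
variation beyond white noise. Passing recovery tests therefore shows the
workflow is correct and well-conditioned at realistic data densities —
not that the pool model is an adequate description of any particular
field site.

## Problem sizes and numerical checks

The test suite and the acceptance script use, as the package's standard
experimental sizes: 20 replicate eight-site studies (10% SOC CV) for
parameter recovery, judged by the median recovered high-N effect and
median relative error of `f_S(0)`; 50 (25 in the script) replicate
two-site studies with 400-draw Monte-Carlo runs for interval coverage
against the known noiseless SOC; 400+ random kinetics/forcing
configurations for monthly carbon-balance closure (tolerance 1e-9
relative, achieved at ~1e-15); and dense (annual observation, noiseless)
two-site studies for Michaelis-Menten recovery, which probes structural
identifiability of `(vmax, km)` separately from noise robustness — with
10% observation noise those two constants are strongly correlated along a
`vmax/km` ridge and individual recovery degrades, which is itself a
finding about the variant's weaker identifiability.

## Known limitations

* Decay coefficients and flow fractions default to one published
  parameterization; users fitting other soils should review them.
* The fitted effects are class means; no continuous dose-response for N
  rate is provided.
* No Bayesian posterior sampling; uncertainty is linearized-Gaussian in
  the transformed space.
* `defac` uncertainty is not propagated; intervals reflect parameter and
  (optionally) observation uncertainty only.
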