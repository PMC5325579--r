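# socfit

Inverse modeling of soil organic carbon (SOC) dynamics in agricultural
soils, built around a monthly surrogate of the CENTURY model family's SOC
sub-model.

## The problem

Long-term field experiments record grain yields, management (tillage,
nitrogen fertilization, organic amendments) and a handful of dated SOC
measurements over decades. Process models of SOC turnover can simulate
these systems, but their predictions hinge on quantities that are rarely
measured directly: how the initial SOC stock is distributed among
conceptual pools of different turnover time, and how strongly management
accelerates decay. `socfit` estimates those quantities statistically, by
fitting the pool model to the observed SOC time series with nonlinear
least squares, and quantifies the resulting uncertainty with Monte-Carlo
simulation. It is aimed at soil biogeochemists and carbon-accounting
modelers who want calibration to be reproducible and to come with standard
errors rather than hand-tuned values.

## The model

Eight pools are tracked: surface and soil structural and metabolic litter,
a surface microbial pool, and the active (A), slow (S) and passive (P)
soil organic matter pools. Each pool obeys a mass balance

    dC_j/dt = sum_i x_{i,j} v_i + u_j - v_j,      v_j = k*_j C_j,

where `x_{i,j}` is the fraction of decomposed carbon flowing from pool *i*
to pool *j*, `u_j` the litter input, and the monthly rate coefficient
composes a maximum rate with multiplicative modifiers:

    k*_j = (k0_j / 12) * defac * texture_j * lignin_j * mgmteff_j.

`defac` is the supplied abiotic (temperature x moisture) factor, and
`mgmteff = clteff * ferteff * omeff` multiplies decay of the active and
slow pools only. The tillage effect `clteff` is fixed (5.5 in the tillage
month, or the annualized equivalent 1.4 over the following year);
fertilization and amendment effects are fitted on the log scale per rate
class (N: low <=100, mid 100-200, high >=200 kg N ha⁻¹; OM: mid <=10,
high >10 t DM ha⁻¹), so `ferteff = exp(lambda_FERT) = 1` means no effect.
The monthly system is integrated with the Crank-Nicolson scheme
(second-order, unconditionally stable here) or explicit Euler.

Carbon inputs are derived from observed yields Y via harvest index (HI),
root-to-shoot ratio (RSR), rooting-depth fraction (RD), grain moisture
and residue carbon concentrations,

    AG = Y (100-θ)/100 c_AG (1-HI)/HI f_MIX,
    BG = Y (100-θ)/100 c_BG (RSR/HI) RD,

with `f_MIX` = 0.95 (conventional tillage) or 0.05 (no-till) of
aboveground residue mixed into the soil.

The fitted parameters are the initial slow-pool fraction `f_S(0)` per site
(or per treatment), the log effects `lambda_FERT`/`lambda_OM`, and — in the
Michaelis-Menten variant, which replaces the management multiplier with a
substrate dependence `vmax C_MR/(km + C_MR)` on the metabolic litter pool
— the constants `vmax` and `km`. Estimates come with standard errors from
`sigma² (JᵀJ)⁻¹`, t tests against null effects, R², and Monte-Carlo 95%
prediction intervals.

## Worked example

Generate a synthetic three-site study (known truth: `ferteff(high)` = 1.5,
site `f_S(0)` tied to prior land use, 10% observation noise), fit it, and
compute prediction intervals:

```r
library(socfit)
gs  <- generate_study(synthetic_designs(n_sites = 3, seed = 42),
                      truth_parameters(), seed = 42)
fit <- fit_soc(gs$study)
fit
#> SOC inverse fit: 64 observations, 7 parameters
#> SSR = 1504.5  R^2 = 0.5809
#>
#>               estimate std_error       t p_value
#> f_S[site01]     0.7372    0.0607 12.1414  0.0000
#> f_S[site02]     0.5217    0.0724  7.2031  0.0000
#> f_S[site03]     0.4430    0.0575  7.7033  0.0000
#> ferteff[low]    1.1951    0.2038  0.9574  0.3424
#> ferteff[mid]    1.0766    0.2309  0.3315  0.7415
#> ferteff[high]   1.5230    0.1734  3.0162  0.0038
#> omeff[mid]      1.0975    0.1829  0.5330  0.5961

cfg <- mc_config(n_draws = 500, seed = 99)
iv  <- mc_prediction_interval(fit$problem, draw_parameter_sets(fit, cfg), cfg)
head(iv, 4)
#>     site treatment year observed predicted lower upper
#> 1 site01        T0 1970    62.57     63.74 63.74 63.74
#> 2 site01        T0 1974    53.73     54.10 52.45 56.20
#> 3 site01        T0 1978    43.84     47.39 44.44 51.12
#> 4 site01        T0 1982    35.52     42.53 38.65 47.43
```

The fit recovers the generating high-N decay acceleration (1.52 vs a true
1.5; significantly above 1, p = 0.004) and the site initial slow-pool
fractions; the weakly informed low/mid-N and amendment effects are
correctly found not significantly different from 1. `f_S[site01]` = 0.74
says roughly three quarters of that site's initial SOC turns over on the
decadal timescale of the slow pool — typical of a site coming out of
grassland. The interval table gives observed and predicted SOC
(Mg C ha⁻¹) with 95% Monte-Carlo bounds; the first observation falls at
the simulation start, where the prediction is pinned to the measured
initial stock.

Studies can be read from and written to plain CSV directories
(`read_study()`, `write_study()`), and fits exported with
`write_report()` (JSON parameter summary + residual tables).

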