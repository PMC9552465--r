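# wqsmix

Split-sample **weighted quantile sum (WQS) regression** for count outcomes,
built for environmental-mixture epidemiology: annual death counts aggregated
per small area (census tract), a known population at risk, and a panel of
strongly correlated pollutant concentrations — such as the chemical
components of PM2.5 — whose joint association with mortality is the
estimand.

## The method

Each component concentration is scored into quantile groups (deciles by
default), and the mixture enters the rate model through one index,

    WQS_j = Σ_i w_i q_ij ,   w_i ∈ [0,1],  Σ_i w_i = 1,

inside a quasi-Poisson rate regression

    log E[count_j] = θ0 + θ1·WQS_j + θ2'x_j + log(population_j),

with variance φμ. The data are split 50:50; decile cut points and the
simplex-constrained weights are estimated on the training half (the weights
by averaging over bootstrap resamples whose mixture coefficient is positive
or null), and the validation half provides the quasi-Poisson estimate of
θ1, reported as a mortality rate ratio `exp(θ1)` per index unit —
approximately a one-decile increase in all components at once. The weights
apportion that cumulative association among components, and can be summed
over a priori emission-source groups (fractional assignments supported,
e.g. organic carbon split 50/50 between tailpipe traffic and power-plant
secondary particles).

The package also provides the surrounding study machinery: group-mass
aggregation for source-level WQS models, total-mass and single-pollutant
quasi-Poisson models (penalized-spline confounder smoothing via REML,
Bonferroni-adjusted per-IQR rate ratios), linear interpolation of
census-style covariates between anchor years, descriptive cohort
summaries, and a Gaussian-copula synthetic-data generator with known
ground truth (correlated log-normal exposures, gamma-Poisson overdispersed
counts) so the whole pipeline is testable without restricted mortality
data.

## Worked example

```r
library(wqsmix)

sim <- make_study_like_dataset(n_units = 100, n_years = 8, seed = 42)
fit <- wqs(cardiovascular ~ temperature + humidity + smoking_rate,
           data = sim$data, mix = sim$components,
           population = "population", n_bootstrap = 25, seed = 42)
summary(fit)
#> Weighted quantile sum regression (cardiovascular)
#> Split: 400 training / 400 validation rows; 25/25 bootstraps retained
#> RR 1.0344 (95% CI 1.0176-1.0515) per 1 unit(s) of wqs
#> Validation-model Pearson dispersion: 1.437
#>
#> Weights:
#>  component weight
#>        SO4 0.3243
#>         Ca 0.1814
#>         Si 0.1317
#>        NO3 0.1164
#>         OC 0.1112
#>        ...
```

The generator's truth for this dataset is a rate ratio of 1.05 per index
unit with weights 0.4/0.3/0.2/0.1 on SO4/NO3/NH4/OC: the fitted interval
(1.018–1.052) covers the truth, the dominant weight lands on SO4, and —
as expected with latent correlations up to 0.87 — the remaining weight is
partly diluted across correlated neighbours (Ca, Si) at this small size.
Weight estimates sharpen at the default study scale (500 units × 16 years,
250 bootstraps). Summing the same weights by emission source:

```r
head(sum_group_weights(fit), 4)
#>                    group     weight         components
#> 6 power_plants_secondary 0.49635916 SO4, NO3, OC x 0.5
#> 3                crustal 0.31307769             Si, Ca
#> 5       tailpipe_traffic 0.08436371       EC, OC x 0.5
#> 4   non_tailpipe_traffic 0.07850126     Zn, Pb, Fe, Cu
```

`run_full_study()` drives the complete analysis (three outcomes,
components/groups/drop-one WQS, total-mass and single-component models)
and `write_study_report()` writes CSV tables plus a JSON manifest of
seeds and configuration.

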