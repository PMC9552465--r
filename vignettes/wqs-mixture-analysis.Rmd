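---
title: "Split-sample WQS regression for pollutant mixtures and mortality rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-sample WQS regression for pollutant mixtures and mortality rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqsmix)
```

## The problem

Ambient fine particulate matter (PM2.5) is a mixture. Its chemical
components — major ions and carbon fractions measured in µg/m³, trace
elements in ng/m³ — are strongly and positively correlated with one another,
because they share emission sources and meteorology. Regressing a health
outcome on all components at once therefore produces unstable,
sign-flipping coefficients; regressing on one component at a time
misattributes shared variation. Weighted quantile sum (WQS) regression
addresses both problems for the common epidemiological design in which
annual death counts are aggregated per small area (here called a *unit*,
e.g. a census tract) with a known population at risk.

## The model

Each component concentration is scored into quantile groups (deciles by
default): $q_{ij} \in \{0, \dots, q-1\}$ is the score of component $i$ for
observation $j$. The mixture enters the rate model through a single index

$$\mathrm{WQS}_j = \sum_{i=1}^{p} w_i\, q_{ij}, \qquad
  w_i \in [0, 1], \; \textstyle\sum_i w_i = 1,$$

and the outcome model is a quasi-Poisson rate regression

$$\log E[\text{count}_j] = \theta_0 + \theta_1 \,\mathrm{WQS}_j +
  \boldsymbol\theta_2' \mathbf{x}_j + \log(\text{population}_j),$$

with variance $\varphi \mu$. Because the weights lie on the unit simplex,
one unit of the index is approximately a simultaneous one-quantile increase
in every component, and $e^{\theta_1}$ is the mortality rate ratio for that
increase. The weights themselves apportion the cumulative association among
components.

Estimation is split-sample to avoid overfitting bias:

1. the data are split 50:50 into a training and a validation half;
2. decile cut points are learned on the training half only;
3. on each of $B$ bootstrap resamples of the training half (default
   $B = 250$), $(\theta, w)$ jointly maximize the Poisson likelihood with
   $w$ constrained to the simplex;
4. converged bootstraps whose $\hat\theta_1 \ge 0$ — a positive or null
   mixture association, the direction of interest for inhaled pollutants —
   are retained, and their weight vectors averaged into the final
   $\bar{w}$;
5. the validation half, scored with the *training* cut points, provides the
   quasi-Poisson fit of counts on $\sum_i \bar w_i q_{ij}$ plus covariates,
   whose Wald interval (standard errors scaled by $\sqrt{\hat\varphi}$) is
   the reported cumulative association.

`wqs()` runs the whole procedure and returns a fitted-model object with
`print`, `summary`, `coef`, `weights`, `plot`, `predict` and `residuals`
methods.

```{r example}
sim <- make_study_like_dataset(n_units = 100, n_years = 8, seed = 42)
fit <- wqs(cardiovascular ~ temperature + humidity + smoking_rate,
           data = sim$data, mix = sim$components,
           population = "population", n_bootstrap = 25, seed = 42)
summary(fit)
```

## Design choices

Several details of the procedure are genuinely open, and the package fixes
them as follows.

**Quantile convention.** Cut points are empirical quantiles with linear
interpolation between order statistics (the `type = 7` default of
mainstream statistical software), at probabilities $k/q$. Ties at a cut
fall in the lower bin; validation values outside the fitted range clip to
the extreme bins. Scores are therefore rank-monotone, invariant to strictly
increasing transforms of a component, and deterministic. Cut points are
estimated on the training half only and applied unchanged to the
validation half: estimating them on the full data would leak distributional
information across the split. Constant (zero-variance) components are
retained but warned about — they score 0 everywhere and carry no
information for weighting.

**Simplex handling.** The weights are parameterized as a normalized
exponential (softmax) of unconstrained scores $z$, with $z_1 \equiv 0$ for
identifiability and equal weights ($z = 0$) as the starting point. The
joint likelihood is maximized by a bounded quasi-Newton method (`nlminb`)
with an analytic gradient. Three numerical safeguards matter in practice,
all visible in the code: (i) the softmax scores are boxed at $|z| \le 12$ —
wide enough for effectively one-hot weights, but preventing a line-search
overshoot from stranding the iterate on the plateau where the softmax
gradient vanishes; (ii) a ridge of $10^{-6}\sum z_k^2$ keeps a restoring
gradient on that plateau while perturbing interior optima negligibly;
(iii) covariate columns are standardized internally, since raw covariates
with large means are nearly collinear with the intercept and destroy the
conditioning of the search (the weights, $\theta_1$ and its standard error
are invariant to this reparameterization). Convergence is accepted on
first-order optimality — a scaled projected-gradient test — not merely on
the solver's return code, because along nearly flat simplex directions of
highly correlated mixtures the solver can report "false convergence" at a
point that is already optimal to tolerance. After the weight search, a
plain Poisson GLM at the final weights polishes $\hat\theta_1$ and its
standard error. On two-component problems the optimizer agrees with an
exhaustive profile grid search over $w_1$ — that equivalence is part of the
test suite.

**Direction filter and pooling.** A bootstrap is retained when its point
estimate $\hat\theta_1 \ge 0$; filtering on statistical significance
instead is available (`pooling = "signal_weighted"` weights bootstraps by
the magnitude of the $\hat\theta_1$ t-statistic), but the default is the
plain mean of retained weight vectors, the simplest reading of
"averaging the weights". $\theta_1$ is left unconstrained inside each
bootstrap fit; only the pooling filter enforces direction. Runs in which
more than 20% of bootstraps fail to converge abort with an error rather
than silently pooling a biased subset.

**Resampling unit and seeds.** The bootstrap resamples rows — unit-year
observations of the aggregated analysis dataset. No block bootstrap is
attempted. One master seed drives everything: the split and each
bootstrap's resample get seeds derived deterministically from (master,
index), so any run is reproducible from its manifest, and internal seeding
restores the caller's RNG state.

**Covariates.** Covariates enter the WQS rate models linearly. The
secondary total-mass and single-component quasi-Poisson models can instead
smooth continuous confounders with penalized splines: cubic B-splines on 20
equally spaced knots with a second-order difference penalty, the smoothing
parameter chosen by REML on the working model (`mgcv`), with a fixed-df
override. `build_pspline_smooth()` exposes the basis and penalty
construction directly; its partition-of-unity and penalty-null-space
properties are tested against penalized least squares on the raw matrices.

**Inference conventions.** Dispersion is the Pearson statistic over
$n - p$ (effective degrees of freedom when smooths are present). Intervals
are Wald on the log-rate scale. Single-component models report the rate
ratio per interquartile-range increase, with the IQR computed on the
analysis rows, and Bonferroni-correct the interval level over the $p$
components. Rows with zero population are dropped (with a logged count)
before rate modelling, since the log offset is undefined there.

## Source groups

Components can be assigned a priori — not by formal source apportionment —
to emission source categories, fractionally where a component has more than
one important origin. The default map has eight groups (heavy fuel oil
combustion: V, Ni; biomass burning: K; crustal matter: Si, Ca;
non-tailpipe traffic: Zn, Pb, Fe, Cu; tailpipe traffic: EC + ½OC;
secondary particles from power plants: SO4, NO3 + ½OC; secondary particles
from agriculture: NH4; unclear: Br), with organic carbon split 50/50
between the two groups that both produce it. `sum_group_weights()` sums
pooled weights by group (conserving the simplex exactly — a
single-component group's weight equals that component's weight);
`aggregate_group_mass()` converts everything to µg/m³ and sums shared
masses per group, yielding a valid exposure panel on which `wqs()` can run
the group-level mixture model directly.

## The synthetic-data generator

Real analysis datasets of this design are typically restricted (individual
mortality records), so the package ships a generator whose defaults
emulate the study conditions the method targets, and every pipeline stage
is exercised against its known ground truth.

* **Concentrations** are drawn from a Gaussian copula: a latent
  multivariate normal with a one-factor correlation structure — fourteen
  components with pairwise latent correlations spanning 0.40–0.87 and one
  near-independent component (potassium, latent correlations ≈ 0.04–0.06)
  — mapped through log-normal marginals moment-matched to published
  annual-mean summary statistics (e.g. sulfate mean 2.21, SD 0.75 µg/m³).
  Log-normals are the natural choice for nonnegative, right-skewed ambient
  concentrations. Copula correlations are specified on the latent normal
  scale; the implied Spearman correlation, $\tfrac{6}{\pi}\arcsin(r/2)$,
  is what the tests check.
* **Counts** invert the analysis model: the panel is scored into deciles
  on the full generated data, the true simplex weights (default
  0.4/0.3/0.2/0.1 on the first four components, zero elsewhere) form the
  true index, and counts are drawn from
  $\log \mu = \theta_0 + \theta_1\,\mathrm{WQS} + \boldsymbol\theta_2'
  \mathbf{x} + \log(\text{population})$ — Poisson for $\psi = 1$, or a
  gamma-mixed Poisson with variance $\psi\mu$ for $\psi > 1$ (default
  $\psi = 1.5$, mild extra-Poisson variation as seen in aggregated
  mortality counts).
* **The bundled scenario** (`make_study_like_dataset()`) has 500 units
  observed over 16 years, tract-like adult populations (log-normal, median
  3000), three covariates (annual temperature ~ N(10.1, 1.05 °C), relative
  humidity ~ N(64.5, 2.91%), a smoking-surrogate rate), a common true
  effect of $\theta_1 = \log 1.05$ per index unit for all three outcomes,
  and cause-specific baselines giving annual death rates of roughly 1%
  (non-accidental), 0.35% (cardiovascular) and 0.11% (respiratory) of the
  adult population.

What the generator does *not* emulate: spatial structure (units are
exchangeable; no geography), exposure measurement error from prediction
models, within-unit temporal autocorrelation of exposures beyond what the
shared marginals induce, and population migration. Passing tests therefore
demonstrate that the estimator recovers the truth under a correctly
specified, correlated-mixture rate model at realistic sizes — not that it
is robust to the measurement and confounding pathologies of real exposure
surfaces.

## Scaled-down validation experiments

The acceptance suite (and `scripts/acceptance.R`) measures, at sizes a
single CPU handles in minutes:

* **Simplex conservation** across every bootstrap and pooled weight vector
  of the runs below (over 1000 vectors): entries in $[0,1]$, sums within
  $10^{-8}$ of 1.
* **Oracle equivalence** on twenty seeded two-component toys ($n = 40$):
  the optimizer's $w_1$ against a 101-point profile grid search, within
  0.02.
* **GLM hand checks**: intercept-only fit on counts $\{1, 3\}$ gives
  $\hat\theta_0 = \log 2$, $\hat\varphi = 1$; adding $\log 2$ to the offset
  shifts only the intercept.
* **Weight recovery**: twenty studies of 500 units × 16 years with 50
  bootstraps each; the three largest pooled weights identify the true
  top-three components in at least 90% of runs.
* **Coverage**: two hundred replicates of 125 units × 16 years with 20
  bootstraps, true rate ratio 1.05 per index unit; the validation-half 95%
  interval covers the truth 93–97% of the time.
* **Group conservation**: random simplex weights through the default map
  sum to 1 within $10^{-8}$, and the biomass group weight equals the
  potassium weight exactly.
* **Dispersion round trip**: data generated at $\psi \in \{1, 2\}$ on 50k
  rows return a Pearson dispersion within ±10%.

These problem sizes are the package's chosen desk-scale defaults for the
experiments; the full-size procedure (250 bootstraps on larger panels) is
the same code path.

## Limitations

The estimator inherits WQS's known caveats: weights are identified only up
to the information the bootstrap likelihoods carry, and within a highly
correlated cluster weights can be diluted across members — dropping a
cluster member (the `drop =` sensitivity) probes exactly this. The
direction filter makes the method one-sided by construction; a mixture
with genuinely protective members needs the `direction = "negative"` run.
Repeated-holdout WQS variants, quantile g-computation, and
component-interaction models are out of scope, as are spatially explicit
simulation and formal source apportionment.
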