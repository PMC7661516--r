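---
title: "Models and methods in reefhurdle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in reefhurdle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

reefhurdle analyses stationary visual-census surveys of a reef fish
sampled across a mosaic of marine protected areas: where are the juvenile
nursery hotspots, and how has abundance changed over the survey years?
This vignette explains each model in the pipeline, the assumptions behind
it, the tunable parameters and their defaults, and the design choices that
were genuinely open.

## Survey design and density arithmetic

A stationary visual census counts every individual inside a disc of fixed
radius around a diver: density is $N / (\pi r^2)$. The emulated design
uses $r = 2$ m for juveniles and $r = 4$ m for adults, with juveniles
defined as individuals of total length $\le 10$ cm (the boundary is
juvenile; both the radius pairing and the threshold are configurable).
`census_area()` is exact; `census_area_printed()` reproduces the
field-report convention of computing disc areas with $\pi$ to two
decimals (giving the conventional 12.6 and 50.2 m² — exact $\pi$ would
print 50.3 for the 4 m radius), because printed survey tables follow that
convention.

Mean density per location is total individuals divided by the number of
censuses — a mean count per census, not per m²; `aggregate_mean_density()`
offers a `per_m2` flag for the latter.

## Permutation ANOVA and pairwise contrasts

Densities from visual censuses are zero-inflated and far from normal, so
group comparisons use a permutation ANOVA: the usual one-way F statistic,
with a null distribution built by permuting group labels uniformly at
random. In a one-way layout, label permutation is exact under
exchangeability, which is why labels (not residuals) are permuted. The
p-value uses the add-one convention $p = (1 + \#\{F^* \ge F\}) / (1 + m)$,
the standard bias-safe estimator that can never return zero; its smallest
attainable value is $1/(m+1)$. The default `iterations = 5000` follows
the emulated analysis; the null-calibration test uses 499 permutations per
replicate, which resolves the 0.05 level exactly while keeping 500
replicates affordable.

Post-hoc contrasts are two-sample permutation tests on the absolute
difference of group means, adjusted for multiplicity (Holm by default —
the emulated analysis does not name an adjustment; `"BH"` and `"none"`
are available). The compact letter display assigns a letter to every
maximal clique of the "not significantly different" graph, so two groups
share a letter exactly when all contrasts within that clique are
non-significant at the chosen level. When all contrasts are significant
after adjustment but not before, the raw and adjusted tables will
disagree; both are reported.

## The two-stage hurdle (delta) model

Juvenile counts are mostly zero. The hurdle model splits the analysis:

1. **Occurrence** — presence/absence of juveniles per census,
   $z_i \sim \mathrm{Bernoulli}(p_i)$, $\mathrm{logit}(p_i) = \eta_i$;
2. **Positive density** — the strictly positive densities only,
   $y_i \sim \mathrm{Gamma}(a,\, a / \mu_i)$, $\log \mu_i = \eta_i$,
   with shape $a$ estimated.

Both stages share the same linear-predictor structure with independent
parameters:

$$\eta_i = \mathbf{x}_i^\top \boldsymbol\beta + \gamma_{\text{year}(i)}
  + b_{\text{obs}(i)} + w(s_i)$$

* **Fixed effects** $\boldsymbol\beta$ over benthic covers and
  environmental covariates, with vague Normal$(0, 100)$ priors.
  Continuous covariates are centred and scaled by training-set statistics
  (stored, and reused verbatim at prediction time); binary covariates
  (rugosity) are left untouched; interaction columns are products of the
  standardized mains.
* **Year factor** $\gamma$, dummy-coded with the first survey year as
  reference, treated as fixed effects under the same prior.
* **Observer effect** $b_j \sim N(0, \sigma_o^2)$ with a half-Normal(0,
  $2^2$) hyperprior on $\sigma_o$.
* **Spatial field** $w$, a zero-mean Gaussian process over site
  coordinates (planar km; the study extent of a few hundred km tolerates
  a local projection) with Matérn($\nu = 1$) covariance
  $C(d) = \sigma_w^2 (\kappa d) K_1(\kappa d)$, $\kappa = \sqrt{8\nu}/\rho$,
  so the practical range $\rho$ is the distance at which correlation has
  fallen to about 0.13. Hyperpriors: half-Normal(0, $2^2$) on $\sigma_w$,
  log-Normal($\log 20$ km, $1$) on $\rho$. The field is static and shared
  across years; temporal structure enters through the year factor. A
  full-rank GP is affordable because the designs here have 28–100 sites.

Modelling the per-census *density* (count / area) with a Gamma likelihood
accepts a discreteness-induced misspecification — densities from small
counts sit on a lattice. The synthetic generator's continuous mode exists
precisely to provide well-specified recovery tests; the count mode
reproduces the lattice that real data would show.

### Inference

Inference is a self-contained seeded adaptive Metropolis-within-Gibbs
sampler:

* $\boldsymbol\beta$: multivariate random-walk block, initialized at the
  corresponding GLM estimate with its covariance as the proposal shape,
  then adapted (Haario-style covariance during burn-in, Robbins–Monro
  scaling toward 0.25 acceptance);
* observer effects: joint random-walk block; $\sigma_o$ on the log scale;
* field values: preconditioned Crank–Nicolson moves, which leave the GP
  prior invariant so acceptance depends on the likelihood alone;
* field hyperparameters: joint log-scale random walk, with the exact GP
  density of the current field values in the acceptance ratio;
* Gamma shape: log-scale random walk with a Gamma(2, 0.5) prior.

Every run is bit-reproducible given a seed. Observations are put in a
canonical order (site, year, observer, count) before sampling, so
posterior summaries do not depend on input row order. Per-observation
log-likelihood draws are stored for WAIC and CPO.

### Prediction and hotspots

Per grid cell the model reports the posterior-mean presence probability
$\hat p$, the posterior-mean conditional density $\hat\mu$, and the delta
expectation $\hat p \, \hat\mu$ — the two components are also kept
separately, since the combined product is an operationalization rather
than something the two-stage fit defines by itself. The field is
interpolated to cells by its conditional (kriging) mean; the kriging
weights use posterior-mean field hyperparameters (one Cholesky
factorization) applied to the posterior draws of the site-level field — a
speed/accuracy trade that ignores hyperparameter uncertainty in the
interpolation weights but keeps field-value uncertainty. Cells missing a
covariate are flagged, never imputed. Nursery hotspots are the cells at
or above the 0.9 quantile of expected density (ties kept; quantile
configurable).

## Model evaluation and selection

* **WAIC** $= -2\sum_i[\log \frac1S\sum_s e^{\ell_{si}} -
  \mathrm{Var}_s(\ell_{si})]$, computed stably via log-sum-exp.
* **CPO** per observation by the harmonic-mean identity; the summary is
  LCPO $= -\frac1n\sum\log \mathrm{CPO}_i$, so "low CPO" means low LCPO
  (raw CPO is larger-is-better).
* **RMSE**, **Pearson r**, **R²** (the squared Pearson correlation of
  observations with posterior-mean predictions — an "adjusted" variant by
  $n$ and parameter count is available but not default, since the
  original adjustment is not reproducible from the description), and
  **AVEerror**, implemented as mean absolute error (the term is cited to
  an external definition; the implementation is swappable).

**Variable selection** starts from the full main-effects specification
and iteratively drops the predictor whose 95% credible interval most
widely covers zero (smallest max-over-stages $|\hat\beta|/\mathrm{sd}$),
until every remaining predictor excludes zero in at least one stage —
relevance in either stage counts, because a single functional response
per predictor is reported while two coefficient sets are fitted. Visited
specifications are ranked by the compromise of low WAIC, low RMSE and
high R² (rank sum; ties to fewer terms, then lower WAIC). A search over
*all* interactions of twelve covariates is combinatorially infeasible;
pairwise interactions can be declared explicitly and are capped to
predictors surviving a main-effects screen.

**Cross-validation** repeats ten times: a seeded random half of the
censuses trains the model, the held-out half is predicted, and Pearson r
and AVEerror are computed per repeat and pooled. (A "tenfold cross
validation using a random half" conflates k-fold and split-half; repeated
split-half is implemented, and this reading is flagged rather than
silently resolved.) Degenerate training halves — no presences or no
absences — are redrawn a bounded number of times.

## Latent Poisson trend models

Yearly totals per location (sites aggregated) are modelled as
$y_t \sim \mathrm{Poisson}(e^{\mu + u_t})$ with three latent priors:

* **AR1**: stationary, $u_t = \rho u_{t-1} + \varepsilon_t$,
  $\varepsilon_t \sim N(0, \tau^{-1})$, $u_1 \sim N(0, \tau^{-1}/(1-\rho^2))$;
* **RW1**: $\Delta u_t \sim N(0, \tau^{-1})$ — locally constant trends;
* **RW2**: $\Delta^2 u_t \sim N(0, \tau^{-1})$ — locally linear trends.

Priors: $\mu \sim N(0, 100)$ (matching the fixed-effect variance used
elsewhere), $\tau \sim \mathrm{Gamma}(1, 0.01)$ (vague, conjugate, so
$\tau$ has a Gibbs update), and for AR1 a vague Normal(0, precision 0.15)
prior on $\mathrm{logit}((\rho+1)/2)$ — the conventional default for this
transform. A standard-normal prior there looks innocuous but visibly
shrinks the posterior median of $\rho$ toward zero on 20–30-year series
— exactly the series lengths this package targets — while the vaguer
prior leaves it essentially centred. Even then, the posterior median of
$\rho$ inherits the realized path's own lag-1 autocorrelation, which
varies substantially from draw to draw at these lengths: the recovery
test therefore asserts a clear-majority rate, a property of short
series rather than of the estimator.
$\rho$ is updated twice per sweep — a centred step with the latent path
held fixed, interleaved with a non-centred step that holds the
innovations fixed and rebuilds the path under the proposed $\rho$, which
breaks the strong coupling that makes centred-only samplers sticky.
The RW priors are improper in the level, so
the reported trajectories are centred (sum-to-zero) with the level moved
into $\mu$; a likelihood-invariant level-swap move keeps that split
mixing. Latent values are updated by vectorized single-site Metropolis
steps in checkerboard classes (stride 2, or 3 for RW2, so sites within a
class share no prior term); RW2 gets an extra prior-invariant global
slope move. Gap years inside the observed range are carried by the
latent process without contributing likelihood. Counts, not densities,
are modelled: that is what a Poisson likelihood is for, and effort is
reported alongside (an optional log-effort offset is available but
off by default, matching an analysis of raw aggregated abundance).

**Exclusion guard.** Series with total count below `min_total = 10` are
excluded with a reason (a series of 9 individuals over six years cannot
support a trend model — the default is motivated by exactly such a case),
and specific years can be dropped (e.g. years with too few censuses).
Both rules are explicit configuration, never silent.

**Model choice** fits all three (RW2 needs four observed years) and
ranks by WAIC and LCPO (rank sum). The final choice is the best *and most
parsimonious* model: when a simpler model — RW1, with a single
hyperparameter — lies within `parsimony_margin = 2` WAIC units of the
rank-sum winner, it is preferred. The margin of 2 is the conventional
practical-equivalence threshold for information criteria, not a fitted
quantity; sampler-based WAIC on six-to-twenty-point series carries
Monte-Carlo noise of the same order as the true AR1–RW1 gap, and without
the margin the "most parsimonious" clause would never fire because exact
ties have probability zero. Setting `parsimony_margin = 0` recovers the
strict rank-sum rule.

**Trend direction** between two fitted years is the posterior probability
that the latent log-mean declined; $\ge 0.9$ is reported as declining,
$\le 0.1$ as increasing, otherwise flat (thresholds configurable).

## The synthetic-data generator

Every analysis stage is testable without field data because the generator
draws datasets with exactly the statistical structure the models assume:
28 reef sites nested in six named locations across four MPA regimes;
years 2003–2008 with two offshore locations starting 2005; a configurable
number of stationary censuses per site and year (25 by default, giving a
few thousand censuses per life stage, the order of the emulated survey);
presence and positive density driven by benthic/environmental covariates
through the same standardization the model applies (so stated
coefficients are recovered on their own scale); a Matérn field (sd 1,
range 15 km); observer effects (sd 0.3); a declining shared year effect
(−0.15 per year) with per-location adjustments for scenario trends; and
covers built by a logistic-normal (softmax) construction that always sums
to at most 1. Environmental ranges are plausible for shallow tropical
reefs (SST 24–28 °C, SSS 36–38 PSU, depth 0.5–27 m).

Two response modes matter:

* `continuous` records the exact Gamma density (count = its ceiling on
  the census area, at least 1) — data that satisfy the hurdle likelihood
  exactly, making parameter-recovery tests well-posed; the ceiling is a
  documented distortion of the count column only.
* `count` draws integer counts as $1 + \mathrm{Poisson}(\mu \cdot
  \text{area} - 1)$ clipped at zero — the lattice real data would show.

Each generator call derives its RNG stream from (seed, purpose tag), so
covariate and survey randomness are decoupled. The `scenario_abrolhos_like()`
bundle adds hotspot structure at three locations via elevated benthic
covers and gives one offshore location a late-increasing trend. The
scenario is structural, not calibrated: it makes no attempt to match any
real dataset's empirical distributions, so quantities like
cross-validated r on the scenario characterize the pipeline, not the
field system.

## Problem sizes used by the test-suite experiments

Recovery and calibration experiments are sized to be decisive yet
routine: permutation-null calibration uses 500 replicates of 6 × 30
observations at 499 permutations; hurdle coefficient coverage uses 50
replicates of ~500 censuses with 1500 sampler iterations (the
random-effect structure off and balanced site-year design, so the
likelihood is exactly well-specified); selection recovery uses 20
replicates of ~670 censuses with two true and four noise predictors;
trend-model selection uses 50 RW1 series of length 20 at 9000 iterations
per fit, where the longer chains stabilize the WAIC/CPO ranks; field
recovery uses 80 sites in 16 clusters spaced about 12 km apart, because
inter-cluster spacing near the 15 km range is what makes the range
parameter identifiable.

## Known limitations

* The spatial field is static; a time-varying field would need a
  different (e.g. separable space–time) covariance and is out of scope.
* The Gamma stage on per-census densities is misspecified for small
  counts (lattice effects); continuous-mode tests quantify the sampler,
  not that misspecification.
* Kriging weights ignore field-hyperparameter uncertainty (posterior
  means only).
* The CPO harmonic-mean estimator is noisy for influential observations;
  WAIC and CPO are therefore always reported together.
* Passing recovery tests on synthetic data shows the machinery is
  correct under its own assumptions; real surveys add observer drift,
  preferential sampling and covariate measurement error that the
  generator deliberately does not emulate.
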