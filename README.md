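# reefhurdle

Tools for analysing stationary visual-census surveys of reef fish across
a mosaic of marine protected areas, built around two questions that
recur in reef-fish conservation: **where are the juvenile nursery
hotspots**, and **is the population trending up or down** inside the
areas meant to protect it? The motivating system is an endangered,
heavily fished parrotfish surveyed on 28 reefs in six locations over six
years, with juveniles counted in 2 m-radius censuses and adults in 4 m —
but every stage of the pipeline runs on seeded synthetic data with the
same statistical structure, so nothing here requires the field dataset.

## What is in the package

**Survey arithmetic.** Census density is $N / (\pi r^2)$; individuals of
total length ≤ 10 cm are juveniles; per-location mean density is total
individuals over the number of censuses. CSV readers/writers with schema
validation (`read_surveys()`, `read_sites()`).

**Permutation tests.** One-way permutation ANOVA (`perm_anova()`) for
density differences among locations — labels permuted, $p = (1 +
\#\{F^* \ge F\})/(1+m)$ — and pairwise permutation post-hoc tests with
Holm/BH adjustment and a compact letter display
(`pairwise_perm_test()`).

**Hurdle species-distribution model.** A two-stage Bayesian hurdle for
zero-inflated juvenile densities: Bernoulli occurrence with logit link,
then Gamma positive density with log link, each with Normal(0, 100)
fixed-effect priors, an observer random effect, a year factor, and a
Matérn($\nu = 1$) spatial random field over site coordinates. Fitted by
a self-contained seeded adaptive Metropolis-within-Gibbs sampler
(`fit_hurdle()`), with grid prediction $\hat p \cdot \hat\mu$ and
top-decile hotspot masking (`predict_grid()`, `hotspot_cells()`).

**Model evaluation.** WAIC and CPO from per-observation log-likelihood
draws, RMSE / Pearson r / R² / average error, backward variable
selection on the compromise of low WAIC, low RMSE and high R² with 95%
credible intervals deciding relevance (`select_model()`), and repeated
split-half cross-validation (`cross_validate()`).

**Abundance trends.** Latent Poisson models of yearly totals,
$y_t \sim \mathrm{Poisson}(e^{\mu + u_t})$, with AR1, RW1 and RW2 priors
on $u$; model choice by WAIC + CPO rank with a parsimony margin;
low-count exclusion rules; posterior trend direction
(`fit_trend()`, `compare_trends()`, `trend_direction()`,
`series_guard()`).

**Synthetic data.** A seeded generator of the whole survey design —
sites in locations, late-starting offshore locations, excess zeros,
covariate-driven occurrence and density, spatial field, observer and
year effects, per-location trends — plus an `scenario_abrolhos_like()`
bundle with hotspot structure and one late-increasing location
(`sim_config()`, `simulate_covariates()`, `simulate_surveys()`,
`simulate_trend_series()`).

All user-facing functions take a data frame first and return tibbles;
fitted objects have `tidy()`, `glance()` and `autoplot()` methods.
`run_task()` dispatches the pipeline steps (simulate, permtest, fit-sdm,
select, crossval, predict, trends) from a YAML config and writes a JSON
run manifest; `inst/scripts/reefhurdle-cli.R` is a thin shell wrapper.

## Worked example

```r
library(reefhurdle)

bundle <- scenario_abrolhos_like(seed = 1, censuses_per_site_year = 4)
juv <- dplyr::filter(bundle$surveys, life_stage == "juvenile")

# density differences among the six locations
an <- perm_anova(add_census_density(juv), density, location,
                 iterations = 999, seed = 1)
an
#> Permutation-based one-way ANOVA
#>   groups: 6, iterations: 999
#>   SS between = 6.092 (df = 5, MSS = 1.218)
#>   F = 24.17, p = 0.001

# hurdle fit and nursery hotspots
spec <- hurdle_spec(terms = c("turf", "stony_coral", "sst_c"))
fit <- fit_hurdle(juv, bundle$sites, spec, seed = 1,
                  n_iter = 1500, burn = 500)
grid <- hotspot_cells(predict_grid(fit, bundle$sites), q = 0.9)
sum(grid$hotspot)
#> [1] 3
grid$location[grid$hotspot]
#> [1] "TIMB" "PABR" "PABR"

# trend of the locations surveyed from 2003 (the two offshore locations
# only enter the design in 2005, so pooling them confounds effort with
# abundance)
inshore <- dplyr::filter(juv, !location %in% c("ARCH", "PABR"))
region <- aggregate_counts(inshore, group = "all")
cmp <- compare_trends(region, seed = 1)
cmp$chosen
#> [1] "RW1"
trend_direction(cmp$fits[[cmp$chosen]])
#> # A tibble: 1 × 4
#>   from_year to_year direction prob_decline
#>       <int>   <int> <chr>            <dbl>
#> 1      2003    2008 declining            1
```

The ANOVA p-value of 0.001 is the smallest value 999 permutations can
resolve — the six locations genuinely differ (the scenario plants
elevated benthic cover at three of them). The hotspot mask flags the top
decile of predicted expected density: 3 of 28 sites, falling in TIMB and
PABR, two of the three locations where the generator placed elevated
benthic cover. The pooled 2003-start juvenile series is classified as
declining with posterior probability one, matching the declining year
effect the generator injected.

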