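# Shared fixtures: tiny survey tables and fast simulator configurations.

tiny_surveys <- function() {
  tibble::tibble(
    site_id = rep(c("s1", "s2"), each = 3),
    location = rep(c("north", "south"), each = 3),
    mpa_regime = "no-take",
    year = rep(2003:2005, 2),
    observer_id = "obs_1",
    life_stage = "juvenile",
    radius_m = 2,
    count = c(1L, 2L, 0L, 4L, 0L, 3L)
  )
}

# Balanced continuous-mode generator with the random-effect structure off:
# every site is surveyed in every year, so the fitted standardization
# matches the generating one and recovery is well-posed.
recovery_config <- function(seed, beta_bin, beta_gam,
                            censuses_per_site_year = 3,
                            gamma_shape = 2) {
  sim_config(
    censuses_per_site_year = censuses_per_site_year,
    field_sd = 0, observer_sd = 0, year_effect_slope = 0,
    late_start_locations = integer(0),
    mode = "continuous", gamma_shape = gamma_shape,
    beta_bin = beta_bin, beta_gam = beta_gam,
    seed = seed
  )
}

recovery_dataset <- function(seed,
                             beta_bin = c(`(Intercept)` = 0, turf = 0.8,
                                          stony_coral = 0.6),
                             beta_gam = c(`(Intercept)` = -1.5, turf = 0.5,
                                          stony_coral = 0.4),
                             ...) {
  cfg <- recovery_config(seed, beta_bin, beta_gam, ...)
  sites <- simulate_covariates(cfg)
  sim <- simulate_surveys(cfg, sites)
  list(
    surveys = sim$surveys[sim$surveys$life_stage == "juvenile", ],
    sites = sites, truth = sim$truth, config = cfg
  )
}

glm_only_spec <- function(terms) {
  hurdle_spec(terms = terms, observer_effect = FALSE, year_factor = FALSE,
              spatial_field = FALSE)
}
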