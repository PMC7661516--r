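# Seeded synthetic-data generator emulating the survey design: reef sites
# nested in locations and MPA regimes, 2003-2008 with late-starting
# offshore locations, thousands of stationary censuses with excess zeros,
# presence/density driven by benthic and environmental covariates with a
# spatially correlated residual field, observer and year effects, and
# per-location latent abundance trends.

# Deterministic sub-seed per (seed, purpose) so covariate and survey
# randomness are decoupled streams.
tag_seed <- function(seed, tag) {
  v <- utf8ToInt(tag)
  as.integer((as.numeric(seed) * 1000003 + sum(v * seq_along(v))) %%
               2147483647)
}

#' Configure the survey simulator
#'
#' Defaults mirror the study design being emulated: 28 reef sites in 6
#' locations spanning 4 MPA regimes, years 2003-2008 with two offshore
#' locations starting in 2005, and enough stationary censuses to total a
#' few thousand. Hurdle coefficients apply to covariates standardized the
#' same way the model standardizes them, so continuous-mode data satisfy
#' the fitted likelihood exactly.
#'
#' @param n_locations Number of locations.
#' @param sites_per_location Integer vector (recycled) of sites per
#'   location; the default totals 28.
#' @param location_names Optional location labels.
#' @param mpa_regimes Regime per location (recycled).
#' @param years Survey years.
#' @param late_start_locations Indices of locations whose surveys begin at
#'   `late_start_year`.
#' @param late_start_year First survey year for late-starting locations.
#' @param n_observers Number of observers.
#' @param censuses_per_site_year Stationary censuses per site and year.
#' @param beta_bin,beta_gam Named coefficient vectors (must include
#'   `"(Intercept)"`) for the occurrence and density stages; names other
#'   than the intercept must be covariate columns.
#' @param adult_presence_shift Added to the occurrence intercept for the
#'   adult stream (adults are more widespread).
#' @param observer_sd Observer random-effect standard deviation.
#' @param year_effect_slope Per-year linear drift of the shared year
#'   effect on both linear predictors (negative = declining).
#' @param location_year_adjust Optional matrix (locations x years) added
#'   to both linear predictors, for location-specific trends.
#' @param location_covariate_shift Optional named list
#'   `list(covariate = numeric(n_locations))` of additive shifts applied
#'   to simulated covariates, to place hotspot structure.
#' @param field_sd,field_range_km Matérn(nu = 1) field parameters; a field
#'   sd of 0 switches the spatial field off.
#' @param gamma_shape Gamma shape of positive densities.
#' @param mode `"count"` draws integer counts directly; `"continuous"`
#'   draws exact Gamma densities (kept in a `density` column) and stores
#'   the matching ceiling count.
#' @param radius_juvenile_m,radius_adult_m Census radii.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_locations = 6,
                       sites_per_location = c(5, 5, 5, 4, 5, 4),
                       location_names = NULL,
                       mpa_regimes = c("multiple-use", "no-take",
                                       "multiple-use", "open",
                                       "no-take", "no-take"),
                       years = 2003:2008,
                       late_start_locations = c(5, 6),
                       late_start_year = 2005,
                       n_observers = 4,
                       censuses_per_site_year = 25,
                       beta_bin = c(`(Intercept)` = -0.8, turf = 0.8,
                                    stony_coral = 0.6, sst_c = -0.4),
                       beta_gam = c(`(Intercept)` = -2.0, turf = 0.5,
                                    stony_coral = 0.4, sst_c = -0.3),
                       adult_presence_shift = 0.8,
                       observer_sd = 0.3,
                       year_effect_slope = -0.15,
                       location_year_adjust = NULL,
                       location_covariate_shift = NULL,
                       field_sd = 1,
                       field_range_km = 15,
                       gamma_shape = 2,
                       mode = c("count", "continuous"),
                       radius_juvenile_m = 2,
                       radius_adult_m = 4,
                       seed = 1) {
  mode <- match.arg(mode)
  stopifnot(!is.null(seed), observer_sd >= 0, field_sd >= 0,
            gamma_shape > 0)
  if (is.null(location_names)) {
    location_names <- paste0("loc_", seq_len(n_locations))
  }
  stopifnot("(Intercept)" %in% names(beta_bin),
            "(Intercept)" %in% names(beta_gam))
  structure(
    list(
      n_locations = n_locations,
      sites_per_location = rep_len(sites_per_location, n_locations),
      location_names = location_names,
      mpa_regimes = rep_len(mpa_regimes, n_locations),
      years = years,
      late_start_locations = late_start_locations,
      late_start_year = late_start_year,
      n_observers = n_observers,
      censuses_per_site_year = censuses_per_site_year,
      beta_bin = beta_bin, beta_gam = beta_gam,
      adult_presence_shift = adult_presence_shift,
      observer_sd = observer_sd,
      year_effect_slope = year_effect_slope,
      location_year_adjust = location_year_adjust,
      location_covariate_shift = location_covariate_shift,
      field_sd = field_sd, field_range_km = field_range_km,
      gamma_shape = gamma_shape, mode = mode,
      radius_juvenile_m = radius_juvenile_m,
      radius_adult_m = radius_adult_m,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate per-site covariates
#'
#' Site coordinates are clustered around location centres on a planar km
#' grid; the seven benthic cover fractions come from a logistic-normal
#' (softmax with a free "bare substrate" category) so they always sum to
#' at most 1; SST and SSS are Gaussian around location means inside
#' plausible reef ranges (SST 24-28 deg C, SSS 36-38 PSU); depth is
#' log-normal; rugosity is Bernoulli; distance to land derives from the
#' cross-shore coordinate.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A site-covariate tibble (see [read_sites()]) plus `location`
#'   and `mpa_regime` columns.
#' @export
simulate_covariates <- function(config, seed = config$seed) {
  set.seed(tag_seed(seed, "covariates"))
  n_loc <- config$n_locations
  # location centres: an inshore-offshore mosaic over ~200 x 120 km
  centre_x <- stats::runif(n_loc, 5, 70)
  centre_y <- seq(0, 180, length.out = n_loc) + stats::rnorm(n_loc, 0, 5)
  cover_base <- c(turf = 0.0, cca = -0.8, fire_coral = -2.2,
                  macroalgae = -1.2, sponge = -2.0, stony_coral = -0.6,
                  zoanthid = -2.4)
  rows <- purrr::map_dfr(seq_len(n_loc), function(l) {
    n_sites <- config$sites_per_location[l]
    x <- centre_x[l] + stats::rnorm(n_sites, 0, 4)
    y <- centre_y[l] + stats::rnorm(n_sites, 0, 4)
    g <- matrix(stats::rnorm(n_sites * 7, 0, 0.5), n_sites, 7,
                byrow = FALSE) +
      matrix(cover_base, n_sites, 7, byrow = TRUE)
    denom <- 1 + rowSums(exp(g))        # implicit bare-substrate category
    covers <- exp(g) / denom
    colnames(covers) <- names(cover_base)
    tibble::tibble(
      site_id = sprintf("L%02dS%02d", l, seq_len(n_sites)),
      location = config$location_names[l],
      mpa_regime = config$mpa_regimes[l],
      x_km = x, y_km = y
    ) |>
      dplyr::bind_cols(tibble::as_tibble(covers)) |>
      dplyr::mutate(
        sst_c = pmin(28, pmax(24, stats::rnorm(n_sites, 24.8 + 0.4 * l, 0.5))),
        sss_psu = pmin(38, pmax(36, stats::rnorm(n_sites, 37, 0.3))),
        depth_m = pmin(27, pmax(0.5, exp(stats::rnorm(n_sites, 1.6, 0.6)))),
        rugosity = stats::rbinom(n_sites, 1, 0.5),
        dist_land_m = pmax(0, .data$x_km) * 1000
      )
  })
  if (!is.null(config$location_covariate_shift)) {
    for (cv in names(config$location_covariate_shift)) {
      shift <- config$location_covariate_shift[[cv]][
        match(rows$location, config$location_names)]
      rows[[cv]] <- rows[[cv]] + shift
      if (cv %in% BENTHIC_COVARIATES) {
        rows[[cv]] <- pmin(0.95, pmax(0, rows[[cv]]))
      }
    }
    # renormalise covers if a shift pushed the sum above 1
    covers <- as.matrix(rows[BENTHIC_COVARIATES])
    s <- rowSums(covers)
    over <- s > 1
    if (any(over)) {
      covers[over, ] <- covers[over, ] / (s[over] + 1e-6)
      rows[BENTHIC_COVARIATES] <- tibble::as_tibble(covers)
    }
  }
  rows
}

# standardized design matrix for the simulator's linear predictors: same
# transform the fitted model applies.
sim_design <- function(sites_rows, beta) {
  terms <- setdiff(names(beta), "(Intercept)")
  spec <- hurdle_spec(terms = terms, observer_effect = FALSE,
                      year_factor = FALSE, spatial_field = FALSE)
  build_design(sites_rows, spec)$X
}

#' Simulate visual-census surveys from a hurdle model
#'
#' Presence of the focal life stage in each census is Bernoulli with
#' logit-linear predictor (covariates + spatial field + observer + year);
#' given presence, the positive density is Gamma with log-linear mean.
#' `"continuous"` mode records the exact Gamma density (the count is its
#' ceiling on the census area, at least 1), so the generated data satisfy
#' the hurdle likelihood exactly; `"count"` mode draws integer counts as
#' 1 + Poisson(mean area density - 1, clipped at 0). The adult stream uses
#' the same coefficients with a more permissive occurrence intercept and
#' the adult census radius.
#'
#' @param config A [sim_config()].
#' @param covariates Output of [simulate_covariates()] for this config.
#' @param seed Optional override of `config$seed`.
#' @return List with `surveys` (census records; continuous mode adds a
#'   `density` column) and `truth` (latent fields, observer effects,
#'   per-census presence probabilities and conditional means, and the
#'   generating parameters).
#' @export
simulate_surveys <- function(config, covariates, seed = config$seed) {
  set.seed(tag_seed(seed, "surveys"))
  n_sites <- nrow(covariates)
  coords <- as.matrix(covariates[, c("x_km", "y_km")])
  w_bin <- w_gam <- rep(0, n_sites)
  if (config$field_sd > 0) {
    L <- t(chol(matern_cov_matrix(coords, config$field_sd,
                                  config$field_range_km)))
    w_bin <- as.vector(L %*% stats::rnorm(n_sites))
    w_gam <- as.vector(L %*% stats::rnorm(n_sites))
  }
  obs_bin <- stats::rnorm(config$n_observers, 0, config$observer_sd)
  obs_gam <- stats::rnorm(config$n_observers, 0, config$observer_sd)
  X_bin <- sim_design(covariates, config$beta_bin)
  X_gam <- sim_design(covariates, config$beta_gam)
  eta_bin_site <- as.vector(X_bin %*% config$beta_bin) + w_bin
  eta_gam_site <- as.vector(X_gam %*% config$beta_gam) + w_gam
  years <- config$years
  year_eff <- config$year_effect_slope * (seq_along(years) - 1)
  loc_adj <- config$location_year_adjust
  loc_of_site <- match(covariates$location, config$location_names)

  one_stream <- function(stage, radius, intercept_shift) {
    recs <- purrr::map_dfr(seq_len(n_sites), function(s) {
      loc <- loc_of_site[s]
      yr_ok <- if (loc %in% config$late_start_locations) {
        years[years >= config$late_start_year]
      } else years
      purrr::map_dfr(yr_ok, function(yr) {
        k <- config$censuses_per_site_year
        yi <- match(yr, years)
        adj <- if (!is.null(loc_adj)) loc_adj[loc, yi] else 0
        obs_id <- sample.int(config$n_observers, k, replace = TRUE)
        eta_b <- eta_bin_site[s] + intercept_shift + obs_bin[obs_id] +
          year_eff[yi] + adj
        eta_g <- eta_gam_site[s] + obs_gam[obs_id] + year_eff[yi] + adj
        p <- stats::plogis(eta_b)
        mu <- exp(eta_g)
        present <- stats::rbinom(k, 1, p)
        area <- pi * radius^2
        if (config$mode == "continuous") {
          dens <- ifelse(present == 1,
                         stats::rgamma(k, shape = config$gamma_shape,
                                       rate = config$gamma_shape / mu),
                         0)
          count <- ifelse(present == 1, pmax(1, ceiling(dens * area)), 0L)
        } else {
          lam <- pmax(0, mu * area - 1)
          count <- ifelse(present == 1, 1L + stats::rpois(k, lam), 0L)
          dens <- count / area
        }
        tibble::tibble(
          site_id = covariates$site_id[s],
          location = covariates$location[s],
          mpa_regime = covariates$mpa_regime[s],
          year = yr,
          observer_id = paste0("obs_", obs_id),
          life_stage = stage,
          radius_m = radius,
          count = as.integer(count),
          density = dens,
          p_true = p,
          mu_true = mu
        )
      })
    })
    recs
  }
  juv <- one_stream("juvenile", config$radius_juvenile_m, 0)
  adu <- one_stream("adult", config$radius_adult_m,
                    config$adult_presence_shift)
  surveys <- dplyr::bind_rows(juv, adu)
  truth <- list(
    field_bin = w_bin, field_gam = w_gam,
    observer_bin = obs_bin, observer_gam = obs_gam,
    year_effect = year_eff,
    p_true = surveys$p_true, mu_true = surveys$mu_true,
    beta_bin = config$beta_bin, beta_gam = config$beta_gam,
    config = config
  )
  surveys$p_true <- NULL
  surveys$mu_true <- NULL
  if (config$mode != "continuous") surveys$density <- NULL
  list(surveys = surveys, truth = truth)
}

#' Simulate a yearly count series from a latent trend model
#'
#' Draws the latent trajectory from the chosen process (stationary AR1,
#' RW1 increments, or RW2 second differences) and yearly counts
#' \eqn{y_t \sim Poisson(e^{\mu + u_t})}.
#'
#' @param model `"AR1"`, `"RW1"` or `"RW2"`.
#' @param params List with `mu` (log-mean level), `tau` (innovation
#'   precision) and, for AR1, `rho`.
#' @param T Number of years (>= 4).
#' @param seed Integer seed.
#' @param start_year First calendar year label.
#' @return List with `series` (tibble `location`, `life_stage`, `year`,
#'   `count`, `effort`) and `latent` (the drawn u).
#' @export
simulate_trend_series <- function(model, params = list(mu = 2, tau = 4,
                                                       rho = 0.6),
                                  T = 20, seed = 1, start_year = 2003) {
  if (!model %in% TREND_MODELS) {
    stop(sprintf("unknown trend model '%s'", model), call. = FALSE)
  }
  stopifnot(T >= 4)
  set.seed(tag_seed(seed, paste0("trend-", model)))
  sd_e <- 1 / sqrt(params$tau)
  u <- switch(model,
    AR1 = {
      rho <- params$rho
      u <- numeric(T)
      u[1] <- stats::rnorm(1, 0, sd_e / sqrt(1 - rho^2))
      for (t in 2:T) u[t] <- rho * u[t - 1] + stats::rnorm(1, 0, sd_e)
      u
    },
    RW1 = cumsum(c(0, stats::rnorm(T - 1, 0, sd_e))),
    RW2 = cumsum(cumsum(c(0, 0, stats::rnorm(T - 2, 0, sd_e))))
  )
  y <- stats::rpois(T, exp(params$mu + u))
  series <- tibble::tibble(
    location = "simulated", life_stage = "juvenile",
    year = start_year + seq_len(T) - 1,
    count = as.integer(y), effort = 1L
  )
  list(series = series, latent = u)
}

#' An Abrolhos-like synthetic scenario
#'
#' A full dataset bundle with the structure of the study system: six named
#' locations over four MPA regimes (28 sites), two offshore locations
#' starting in 2005, juvenile hotspot structure placed at three locations
#' through elevated benthic covariates, declining year effects everywhere
#' except one offshore location whose trend turns upward from 2006.
#'
#' @param seed Integer seed.
#' @param censuses_per_site_year Censuses per site and year (default 25
#'   gives about 3800 censuses per life stage).
#' @return List with `surveys`, `sites`, `truth`, and the `config` used.
#' @export
scenario_abrolhos_like <- function(seed = 1, censuses_per_site_year = 25) {
  loc_names <- c("ITAC", "TIMB", "PPAR", "SEBG", "ARCH", "PABR")
  years <- 2003:2008
  # declining everywhere; PABR (location 6) turns upward from year 4
  adj <- matrix(0, 6, length(years))
  adj[6, 4:6] <- c(0, 0.35, 0.7)
  config <- sim_config(
    location_names = loc_names,
    years = years,
    late_start_locations = c(5, 6),
    censuses_per_site_year = censuses_per_site_year,
    location_year_adjust = adj,
    location_covariate_shift = list(
      turf = c(0, 0.25, 0.18, 0, 0, 0.2),
      stony_coral = c(0, 0.15, 0.1, 0, 0, 0.12)
    ),
    seed = seed
  )
  sites <- simulate_covariates(config)
  sim <- simulate_surveys(config, sites)
  list(surveys = sim$surveys, sites = sites, truth = sim$truth,
       config = config)
}
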