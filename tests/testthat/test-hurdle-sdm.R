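test_that("design construction standardizes, exempts binaries, crosses terms", {
  df <- tibble::tibble(
    site_id = letters[1:5],
    sst_c = c(24, 25, 26, 27, 28),
    sss_psu = c(36.2, 36.8, 37.1, 37.4, 37.9),
    rugosity = c(0, 1, 0, 1, 1)
  )
  d0 <- build_design(df, glm_only_spec(character()))
  expect_equal(dim(d0$X), c(5, 1))
  expect_true(all(d0$X[, 1] == 1))

  d1 <- build_design(df, glm_only_spec("rugosity"))
  expect_equal(unname(d1$X[, "rugosity"]), df$rugosity)

  spec_ia <- hurdle_spec(terms = c("sst_c", "sss_psu"),
                         interactions = "sst_c:sss_psu",
                         observer_effect = FALSE, year_factor = FALSE,
                         spatial_field = FALSE)
  d2 <- build_design(df, spec_ia)
  z1 <- (df$sst_c - mean(df$sst_c)) / sd(df$sst_c)
  z2 <- (df$sss_psu - mean(df$sss_psu)) / sd(df$sss_psu)
  expect_equal(unname(d2$X[, "sst_c:sss_psu"]), z1 * z2, tolerance = 1e-12)
  expect_equal(unname(d2$X[, "sst_c"]), z1, tolerance = 1e-12)

  # stored scaling is reused verbatim on new data
  d3 <- build_design(df[1:2, ], spec_ia, scaling = d2$scaling)
  expect_equal(unname(d3$X[, "sst_c"]), z1[1:2], tolerance = 1e-12)

  dfna <- df
  dfna$sst_c[3] <- NA
  expect_error(build_design(dfna, glm_only_spec("sst_c")), "sst_c")
  expect_error(build_design(df, glm_only_spec("bogus")), "bogus")
})

test_that("presence stage rejects degenerate responses", {
  X <- matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)"))
  spec <- glm_only_spec(character())
  expect_error(fit_presence(rep(1, 20), list(X = X), spec = spec, seed = 1),
               "all-0 or all-1")
  expect_error(fit_presence(rep(0, 20), list(X = X), spec = spec, seed = 1),
               "all-0 or all-1")
})

test_that("density stage rejects non-positive responses", {
  X <- matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)"))
  y <- c(rgamma(19, 2, 1), 0)
  expect_error(fit_density(y, list(X = X), spec = glm_only_spec(character()),
                           seed = 1),
               "positive")
})

test_that("intercept-only posteriors recover analytic targets", {
  set.seed(17)
  X <- matrix(1, 400, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rbinom(400, 1, 0.5)
  fit <- fit_presence(y, list(X = X), spec = glm_only_spec(character()),
                      seed = 2, n_iter = 1500, burn = 500)
  expect_lt(abs(fit$summary$estimate[1] - qlogis(mean(y))), 0.25)

  yg <- rgamma(500, shape = 2, rate = 2 / exp(1))
  Xg <- matrix(1, 500, 1, dimnames = list(NULL, "(Intercept)"))
  fitg <- fit_density(yg, list(X = Xg), spec = glm_only_spec(character()),
                      seed = 3, n_iter = 1500, burn = 500)
  expect_lt(abs(fitg$summary$estimate[1] - 1.0), 0.15)
  shape_est <- fitg$summary$estimate[fitg$summary$term == "shape"]
  expect_lt(abs(shape_est - 2) / 2, 0.5)
})

test_that("posterior means agree with the GLM MLE when the field is off", {
  dat <- recovery_dataset(701)
  spec <- glm_only_spec(c("turf", "stony_coral"))
  fit <- fit_hurdle(dat$surveys, dat$sites, spec, seed = 5,
                    n_iter = 1500, burn = 500)
  df <- fit$data
  Xfit <- build_design(df, spec)$X
  ml <- glm.fit(Xfit, df$present, family = binomial())
  tb <- fit$binomial$summary
  expect_true(all(abs(tb$estimate[1:3] - ml$coefficients) <
                    3 * tb$std.error[1:3]))
  pos <- df$present == 1
  mlg <- glm.fit(Xfit[pos, ], df$density[pos], family = Gamma(link = "log"))
  tg <- fit$gamma$summary[1:3, ]
  expect_true(all(abs(tg$estimate - mlg$coefficients) < 3 * tg$std.error))
})

test_that("hurdle orchestration propagates stage errors and is seed-stable", {
  dat <- recovery_dataset(702)
  zero <- dat$surveys
  zero$count <- 0L
  zero$density <- 0
  spec <- glm_only_spec(c("turf", "stony_coral"))
  expect_error(fit_hurdle(zero, dat$sites, spec, seed = 1), "all-0")

  f1 <- fit_hurdle(dat$surveys, dat$sites, spec, seed = 9,
                   n_iter = 600, burn = 200)
  f2 <- fit_hurdle(dat$surveys, dat$sites, spec, seed = 9,
                   n_iter = 600, burn = 200)
  expect_identical(tidy(f1), tidy(f2))

  # canonical internal sort: shuffling input rows leaves summaries unchanged
  shuffled <- dat$surveys[sample(nrow(dat$surveys)), ]
  f3 <- fit_hurdle(shuffled, dat$sites, spec, seed = 9,
                   n_iter = 600, burn = 200)
  expect_identical(tidy(f1), tidy(f3))
})

test_that("spatial field variance and range are recovered within a factor of 2", {
  # 80 sites in 16 clusters spaced ~12 km apart: inter-cluster distances
  # near the 15 km range make the range parameter identifiable
  cfg <- sim_config(n_locations = 16, sites_per_location = 5,
                    censuses_per_site_year = 8,
                    late_start_locations = integer(0),
                    observer_sd = 0, year_effect_slope = 0,
                    field_sd = 1, field_range_km = 15,
                    beta_bin = c(`(Intercept)` = 0, turf = 0.5),
                    beta_gam = c(`(Intercept)` = -1.5, turf = 0.3),
                    mode = "continuous", seed = 404)
  sites <- simulate_covariates(cfg)
  sim <- simulate_surveys(cfg, sites)
  juv <- sim$surveys[sim$surveys$life_stage == "juvenile", ]
  spec <- hurdle_spec(terms = "turf", observer_effect = FALSE,
                      year_factor = FALSE, spatial_field = TRUE)
  fit <- fit_hurdle(juv, sites, spec, seed = 7, n_iter = 4000, burn = 2000)
  sig_med <- median(fit$binomial$draws$hyper[, "sigma_field"])
  rng_med <- median(fit$binomial$draws$hyper[, "range_field"])
  expect_gt(sig_med, 0.5)
  expect_lt(sig_med, 2)
  expect_gt(rng_med, 7.5)
  expect_lt(rng_med, 30)
})

test_that("grid predictions respect the hurdle algebra and link monotonicity", {
  dat <- recovery_dataset(703)
  spec <- glm_only_spec(c("turf", "stony_coral"))
  fit <- fit_hurdle(dat$surveys, dat$sites, spec, seed = 4,
                    n_iter = 800, burn = 300)
  grid <- predict_grid(fit, dat$sites, mode = "period-mean")
  expect_true(all(grid$p_presence >= 0 & grid$p_presence <= 1))
  expect_true(all(grid$expected_density <= grid$mu_conditional + 1e-12))
  expect_equal(grid$expected_density,
               grid$p_presence * grid$mu_conditional, tolerance = 1e-12)

  # raising a covariate with positive posterior-mean coefficient cannot
  # lower predicted presence
  b_turf <- tidy(fit)
  b_turf <- b_turf$estimate[b_turf$stage == "binomial" &
                              b_turf$term == "turf"]
  expect_gt(b_turf, 0)
  lo <- dat$sites[1, ]
  hi <- lo
  hi$turf <- lo$turf + 0.2
  two <- dplyr::bind_rows(lo, hi)
  two$site_id <- c("new1", "new2")
  g2 <- predict_grid(fit, two, mode = "period-mean")
  expect_gte(g2$p_presence[2], g2$p_presence[1])

  # missing covariates flag the cell rather than imputing
  gm <- dat$sites[1:4, ]
  gm$turf[2] <- NA
  gmiss <- predict_grid(fit, gm, mode = "period-mean")
  expect_true(any(gmiss$missing))
  expect_true(all(is.na(gmiss$expected_density[gmiss$missing])))

  # per-year mode yields one layer per fitted year
  gy <- predict_grid(fit, dat$sites[1:3, ], mode = "per-year")
  expect_equal(nrow(gy), 3 * length(fit$design$year_levels))
})

test_that("hotspot masking keeps ties and shrinks with the quantile", {
  uniform <- tibble::tibble(expected_density = rep(2.5, 20))
  expect_true(all(hotspot_cells(uniform, 0.9)$hotspot))

  distinct <- tibble::tibble(expected_density = seq_len(100) / 10)
  expect_equal(sum(hotspot_cells(distinct, 0.9)$hotspot), 10)
  m1 <- hotspot_cells(distinct, 0.5)$hotspot
  m2 <- hotspot_cells(distinct, 0.8)$hotspot
  expect_true(all(m1[m2]))  # higher quantile is a subset
  expect_error(hotspot_cells(distinct, 1.2), "\\(0, 1\\)")
  allna <- tibble::tibble(expected_density = c(NA_real_, NA_real_))
  expect_error(hotspot_cells(allna, 0.9), "missing")
})
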