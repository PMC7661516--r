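# Direct-summation oracles (naive arithmetic, no log-sum-exp) for small
# log-likelihood matrices.
waic_oracle <- function(ll) {
  lppd <- 0
  p <- 0
  for (i in seq_len(ncol(ll))) {
    lppd <- lppd + log(mean(exp(ll[, i])))
    p <- p + stats::var(ll[, i])
  }
  -2 * (lppd - p)
}
cpo_oracle <- function(ll) {
  vapply(seq_len(ncol(ll)), function(i) 1 / mean(exp(-ll[, i])), numeric(1))
}

test_that("WAIC matches hand arithmetic and the direct-summation oracle", {
  ll <- matrix(c(log(0.5), log(0.25)), nrow = 2)
  res <- waic(ll)
  expect_equal(res$p_waic, stats::var(c(log(0.5), log(0.25))))
  expect_equal(res$waic, -2 * (log(0.375) - res$p_waic), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    nr <- sample(2:5, 1)
    nc <- sample(1:5, 1)
    m <- matrix(rnorm(nr * nc, -2, 1), nrow = nr)
    expect_equal(waic(m)$waic, waic_oracle(m), tolerance = 1e-12)
  }
})

test_that("WAIC degenerate cases behave as defined", {
  # identical draws: point posterior, p_waic = 0
  ll <- matrix(rep(c(log(0.2), log(0.7)), each = 3), nrow = 3)
  res <- waic(ll)
  expect_equal(res$p_waic, 0)
  expect_equal(res$waic, -2 * (log(0.2) + log(0.7)), tolerance = 1e-12)
  # duplicating an observation doubles WAIC
  ll2 <- cbind(ll, ll)
  expect_equal(waic(ll2)$waic, 2 * res$waic, tolerance = 1e-12)
  expect_error(waic(matrix(0, 1, 3)), "2 posterior draws")
})

test_that("CPO is the harmonic-mean predictive density", {
  ll <- matrix(c(log(0.5), log(0.25)), nrow = 2)
  expect_equal(cpo(ll)$cpo, 1 / 3, tolerance = 1e-12)
  # point posterior: CPO equals the likelihood itself
  llp <- matrix(rep(log(0.4), 4), nrow = 4)
  expect_equal(cpo(llp)$cpo, 0.4, tolerance = 1e-12)
  set.seed(22)
  for (i in 1:10) {
    m <- matrix(rnorm(15, -1, 0.8), nrow = 5)
    res <- cpo(m)
    expect_equal(res$cpo, cpo_oracle(m), tolerance = 1e-12)
    expect_equal(res$lcpo, -mean(log(res$cpo)), tolerance = 1e-12)
    # harmonic mean never exceeds the arithmetic mean of the likelihood
    expect_true(all(res$cpo <= colMeans(exp(m)) + 1e-12))
  }
})

test_that("prediction metrics match hand arithmetic and guard degeneracy", {
  m <- prediction_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$ave_error, 0)
  expect_equal(prediction_metrics(c(1, 2, 4), -c(1, 2, 4))$pearson_r, -1)
  m2 <- prediction_metrics(c(0, 1, 2), c(0, 0, 3))
  expect_equal(m2$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m2$ave_error, 2 / 3, tolerance = 1e-12)
  expect_error(prediction_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(prediction_metrics(1, c(1, 2)), "equal length")
})

test_that("RMSE dominates AVEerror and r stays in [-1, 1] on random input", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    o <- rnorm(n, sd = runif(1, 0.1, 5))
    p <- o + rnorm(n, sd = runif(1, 0, 3))
    m <- prediction_metrics(o, p)
    expect_gte(m$rmse, m$ave_error)
    expect_gte(m$pearson_r, -1)
    expect_lte(m$pearson_r, 1)
    expect_gte(m$ave_error, 0)
  }
})

test_that("selection keeps an all-relevant starting spec unchanged", {
  dat <- recovery_dataset(801,
    beta_bin = c(`(Intercept)` = 0, turf = 1.2, stony_coral = 1.0),
    beta_gam = c(`(Intercept)` = -1.5, turf = 1.0, stony_coral = 0.8))
  spec <- glm_only_spec(c("turf", "stony_coral"))
  sel <- select_model(dat$surveys, dat$sites, spec, seed = 2,
                      n_iter = 800, burn = 300)
  expect_equal(nrow(sel$scores), 1)
  expect_setequal(sel$spec$terms, c("turf", "stony_coral"))
  expect_true(sel$all_relevant)
  expect_true(sel$scores$chosen[1])
})

test_that("selection drops noise predictors but keeps true ones", {
  dat <- recovery_dataset(802,
    beta_bin = c(`(Intercept)` = 0, turf = 1, sst_c = -1),
    beta_gam = c(`(Intercept)` = -1.5, turf = 1, sst_c = -1),
    censuses_per_site_year = 4)
  spec <- glm_only_spec(c("turf", "sst_c", "cca", "sponge"))
  sel <- select_model(dat$surveys, dat$sites, spec, seed = 3,
                      n_iter = 800, burn = 300)
  expect_true(all(c("turf", "sst_c") %in% sel$spec$terms))
  # chosen spec has no irrelevant predictor unless flagged
  if (sel$all_relevant) {
    rel <- reefhurdle:::term_relevance(sel$fit, sel$spec$terms)
    expect_true(all(rel$relevant))
  }
})

test_that("cross-validation is deterministic and respects its bounds", {
  dat <- recovery_dataset(803, censuses_per_site_year = 2)
  spec <- glm_only_spec(c("turf", "stony_coral"))
  cv1 <- cross_validate(dat$surveys, dat$sites, spec, folds = 1,
                        seed = 11, n_iter = 600, burn = 200)
  cv2 <- cross_validate(dat$surveys, dat$sites, spec, folds = 1,
                        seed = 11, n_iter = 600, burn = 200)
  expect_identical(glance(cv1), glance(cv2))
  expect_gte(cv1$ave_error, 0)
  expect_equal(nrow(tidy(cv1)), 1)
})

test_that("cross-validation attains high skill on near-noiseless data", {
  # presence nearly certain and a very tight Gamma: observations track the
  # conditional mean, so held-out predictions should correlate strongly
  dat <- recovery_dataset(804,
    beta_bin = c(`(Intercept)` = 4, turf = 0.5),
    beta_gam = c(`(Intercept)` = -1, turf = 1.2),
    gamma_shape = 400, censuses_per_site_year = 3)
  spec <- glm_only_spec("turf")
  cv <- cross_validate(dat$surveys, dat$sites, spec, folds = 2,
                       seed = 12, n_iter = 800, burn = 300)
  expect_gte(cv$pearson_r, 0.95)
})
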