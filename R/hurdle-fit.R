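# Seeded adaptive Metropolis-within-Gibbs inference for the two hurdle
# stages: Bernoulli occurrence (logit link) and Gamma positive density
# (log link), each with fixed effects, an optional observer random effect,
# an optional year factor (inside the fixed effects) and an optional
# Matérn spatial random field.

log1pexp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# per-observation log-likelihood vectors
loglik_vec_binomial <- function(y, eta) y * eta - log1pexp(eta)
loglik_vec_gamma <- function(y, eta, shape, log_y) {
  shape * (log(shape) - eta) - lgamma(shape) +
    (shape - 1) * log_y - shape * y * exp(-eta)
}

mvn_chol_logdens <- function(w, L) {
  z <- forwardsolve(L, w)
  -sum(log(diag(L))) - 0.5 * sum(z^2) - 0.5 * length(w) * log(2 * pi)
}

# Robbins-Monro style scale adaptation with diminishing step size.
adapt_scale <- function(s, accepted, iter, target, lo = 1e-5, hi = 1e3) {
  step <- min(0.25, 5 / sqrt(iter + 10))
  min(hi, max(lo, s * exp(step * ((accepted) - target))))
}

summarise_draws_matrix <- function(draws, names) {
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    term = names,
    estimate = colMeans(draws),
    std.error = apply(draws, 2, stats::sd),
    conf.low = qs[1, ],
    conf.high = qs[2, ]
  )
}

# One hurdle stage. `family` picks the likelihood; random-effect structure
# is controlled by the spec and by whether obs_idx / coords are supplied.
fit_stage <- function(y, design, family = c("binomial", "gamma"),
                      coords = NULL, site_idx = NULL, obs_idx = NULL,
                      spec = hurdle_spec(), seed = 1,
                      n_iter = 3000, burn = 1000, thin = 2,
                      n_obs_levels = NULL) {
  family <- match.arg(family)
  X <- design$X
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (family == "binomial") {
    if (all(y == 0) || all(y == 1)) {
      stop("occurrence response is all-0 or all-1; the presence stage is undefined (complete separation).",
           call. = FALSE)
    }
  } else {
    if (any(y <= 0)) {
      stop("density stage requires strictly positive responses.",
           call. = FALSE)
    }
  }
  set.seed(seed)
  p <- ncol(X)
  use_obs <- spec$observer_effect && !is.null(obs_idx)
  use_field <- spec$spatial_field && !is.null(coords) && !is.null(site_idx)
  if (use_obs && is.null(n_obs_levels)) n_obs_levels <- max(obs_idx)
  if (!use_obs) n_obs_levels <- 0L
  n_sites <- if (use_field) nrow(coords) else 0L
  hy <- spec$hyper
  prior_sd <- spec$prior_fixed_sd
  log_y <- if (family == "gamma") log(y) else NULL

  ll_sum <- function(eta, shape) {
    if (family == "binomial") {
      sum(y * eta - log1pexp(eta))
    } else {
      n * shape * log(shape) - shape * sum(eta) - n * lgamma(shape) +
        (shape - 1) * sum(log_y) - shape * sum(y * exp(-eta))
    }
  }
  ll_vec <- function(eta, shape) {
    if (family == "binomial") loglik_vec_binomial(y, eta)
    else loglik_vec_gamma(y, eta, shape, log_y)
  }

  # initialize fixed effects (and proposal shape) from the corresponding GLM
  glm_fit <- tryCatch({
    if (family == "binomial") {
      stats::glm.fit(X, y, family = stats::binomial())
    } else {
      stats::glm.fit(X, y, family = stats::Gamma(link = "log"))
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  beta <- rep(0, p)
  prop_chol <- diag(p)
  if (!is.null(glm_fit) && all(is.finite(glm_fit$coefficients))) {
    beta <- glm_fit$coefficients
    qrR <- qr.R(glm_fit$qr)
    vc <- tryCatch(chol2inv(qrR), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(vc))) {
      prop_chol <- tryCatch(t(chol(vc + diag(1e-8, p))),
                            error = function(e) diag(p))
    }
  }
  s_beta <- 1.2

  b <- rep(0, n_obs_levels)
  sigma_obs <- 0.5
  s_b <- 0.2
  s_lso <- 0.5
  w <- rep(0, n_sites)
  sigma_w <- 1
  range_w <- exp(hy$range_meanlog)
  s_pcn <- 0.2
  s_hyp <- 0.4
  if (use_field) {
    L_w <- t(chol(matern_cov_matrix(coords, sigma_w, range_w)))
  }
  shape <- if (family == "gamma") {
    if (!is.null(glm_fit)) {
      mu0 <- exp(as.vector(X %*% beta))
      max(0.2, min(50, 1 / max(1e-3, mean((y / mu0 - 1)^2))))
    } else 1
  } else NA_real_
  s_lsh <- 0.3

  eta_fix <- as.vector(X %*% beta)
  eta_obs <- if (use_obs) b[obs_idx] else 0
  eta_fld <- if (use_field) w[site_idx] else 0
  eta <- eta_fix + eta_obs + eta_fld
  cur_ll <- ll_sum(eta, shape)
  cur_beta_prior <- sum(stats::dnorm(beta, 0, prior_sd, log = TRUE))

  n_save <- floor((n_iter - burn) / thin)
  beta_draws <- matrix(NA_real_, n_save, p)
  hyper_draws <- matrix(NA_real_, n_save, 4)  # sigma_obs, sigma_w, range, shape
  b_draws <- if (use_obs) matrix(NA_real_, n_save, n_obs_levels) else NULL
  w_draws <- if (use_field) matrix(NA_real_, n_save, n_sites) else NULL
  loglik_draws <- matrix(NA_real_, n_save, n)
  acc <- c(beta = 0, b = 0, field = 0, hyper = 0)

  # running moments for the beta proposal (adapted during burn-in)
  beta_mean <- beta
  beta_m2 <- matrix(0, p, p)
  n_adapt <- 0

  save_i <- 0L
  for (it in seq_len(n_iter)) {
    ## fixed effects block
    prop <- beta + s_beta * as.vector(prop_chol %*% stats::rnorm(p))
    eta_fix_p <- as.vector(X %*% prop)
    eta_p <- eta_fix_p + eta_obs + eta_fld
    prop_prior <- sum(stats::dnorm(prop, 0, prior_sd, log = TRUE))
    ll_p <- ll_sum(eta_p, shape)
    a_ok <- log(stats::runif(1)) < (ll_p + prop_prior - cur_ll - cur_beta_prior)
    if (isTRUE(a_ok)) {
      beta <- prop; eta_fix <- eta_fix_p; eta <- eta_p
      cur_ll <- ll_p; cur_beta_prior <- prop_prior
      if (it > burn) acc["beta"] <- acc["beta"] + 1
    }
    s_beta <- adapt_scale(s_beta, as.numeric(isTRUE(a_ok)), it, 0.25)
    if (it <= burn) {
      n_adapt <- n_adapt + 1
      d <- beta - beta_mean
      beta_mean <- beta_mean + d / n_adapt
      beta_m2 <- beta_m2 + tcrossprod(d, beta - beta_mean)
      if (n_adapt >= 50 && it %% 100 == 0) {
        covb <- beta_m2 / (n_adapt - 1) + diag(1e-8, p)
        ch <- tryCatch(t(chol(covb)), error = function(e) NULL)
        if (!is.null(ch)) {
          prop_chol <- ch
          s_beta <- 2.38 / sqrt(p)
        }
      }
    }

    ## observer effects and their sd
    if (use_obs) {
      b_p <- b + s_b * stats::rnorm(n_obs_levels)
      eta_obs_p <- b_p[obs_idx]
      eta_p <- eta_fix + eta_obs_p + eta_fld
      ll_p <- ll_sum(eta_p, shape)
      dprior <- sum(stats::dnorm(b_p, 0, sigma_obs, log = TRUE)) -
        sum(stats::dnorm(b, 0, sigma_obs, log = TRUE))
      a_ok <- log(stats::runif(1)) < (ll_p - cur_ll + dprior)
      if (isTRUE(a_ok)) {
        b <- b_p; eta_obs <- eta_obs_p; eta <- eta_p; cur_ll <- ll_p
        if (it > burn) acc["b"] <- acc["b"] + 1
      }
      s_b <- adapt_scale(s_b, as.numeric(isTRUE(a_ok)), it, 0.25)

      ls <- log(sigma_obs)
      ls_p <- ls + s_lso * stats::rnorm(1)
      sig_p <- exp(ls_p)
      dpost <- sum(stats::dnorm(b, 0, sig_p, log = TRUE)) -
        sum(stats::dnorm(b, 0, sigma_obs, log = TRUE)) +
        (-0.5 * (sig_p / hy$obs_sd_scale)^2 + log(sig_p)) -
        (-0.5 * (sigma_obs / hy$obs_sd_scale)^2 + log(sigma_obs))
      a_ok <- log(stats::runif(1)) < dpost
      if (isTRUE(a_ok)) sigma_obs <- sig_p
      s_lso <- adapt_scale(s_lso, as.numeric(isTRUE(a_ok)), it, 0.44)
    }

    ## spatial field (preconditioned Crank-Nicolson: prior-invariant move,
    ## acceptance depends on the likelihood only)
    if (use_field) {
      s_use <- min(0.999, s_pcn)
      w_p <- sqrt(1 - s_use^2) * w +
        s_use * as.vector(L_w %*% stats::rnorm(n_sites))
      eta_fld_p <- w_p[site_idx]
      eta_p <- eta_fix + eta_obs + eta_fld_p
      ll_p <- ll_sum(eta_p, shape)
      a_ok <- log(stats::runif(1)) < (ll_p - cur_ll)
      if (isTRUE(a_ok)) {
        w <- w_p; eta_fld <- eta_fld_p; eta <- eta_p; cur_ll <- ll_p
        if (it > burn) acc["field"] <- acc["field"] + 1
      }
      s_pcn <- adapt_scale(s_pcn, as.numeric(isTRUE(a_ok)), it, 0.25,
                           lo = 1e-4, hi = 0.999)

      ## field hyperparameters (marginal sd, range)
      lsig <- log(sigma_w); lrng <- log(range_w)
      lsig_p <- lsig + s_hyp * stats::rnorm(1)
      lrng_p <- lrng + s_hyp * stats::rnorm(1)
      sig_p <- exp(lsig_p); rng_p <- exp(lrng_p)
      L_p <- tryCatch(
        t(chol(matern_cov_matrix(coords, sig_p, rng_p))),
        error = function(e) NULL
      )
      if (!is.null(L_p)) {
        dpost <- mvn_chol_logdens(w, L_p) - mvn_chol_logdens(w, L_w) +
          (-0.5 * (sig_p / hy$field_sd_scale)^2 + log(sig_p)) -
          (-0.5 * (sigma_w / hy$field_sd_scale)^2 + log(sigma_w)) +
          stats::dnorm(lrng_p, hy$range_meanlog, hy$range_sdlog, log = TRUE) -
          stats::dnorm(lrng, hy$range_meanlog, hy$range_sdlog, log = TRUE)
        a_ok <- log(stats::runif(1)) < dpost
        if (isTRUE(a_ok)) {
          sigma_w <- sig_p; range_w <- rng_p; L_w <- L_p
          if (it > burn) acc["hyper"] <- acc["hyper"] + 1
        }
        s_hyp <- adapt_scale(s_hyp, as.numeric(isTRUE(a_ok)), it, 0.25)
      }
    }

    ## Gamma shape
    if (family == "gamma") {
      la <- log(shape)
      la_p <- la + s_lsh * stats::rnorm(1)
      shape_p <- exp(la_p)
      ll_p <- ll_sum(eta, shape_p)
      dpost <- ll_p - cur_ll +
        stats::dgamma(shape_p, hy$shape_shape, rate = hy$shape_rate, log = TRUE) -
        stats::dgamma(shape, hy$shape_shape, rate = hy$shape_rate, log = TRUE) +
        la_p - la
      a_ok <- log(stats::runif(1)) < dpost
      if (isTRUE(a_ok)) {
        shape <- shape_p; cur_ll <- ll_p
      }
      s_lsh <- adapt_scale(s_lsh, as.numeric(isTRUE(a_ok)), it, 0.44)
    }

    if (it > burn && (it - burn) %% thin == 0) {
      save_i <- save_i + 1L
      beta_draws[save_i, ] <- beta
      hyper_draws[save_i, ] <- c(sigma_obs, sigma_w, range_w, shape)
      if (use_obs) b_draws[save_i, ] <- b
      if (use_field) w_draws[save_i, ] <- w
      loglik_draws[save_i, ] <- ll_vec(eta, shape)
    }
  }
  colnames(beta_draws) <- colnames(X)
  colnames(hyper_draws) <- c("sigma_obs", "sigma_field", "range_field", "shape")

  extra <- c(
    if (use_obs) "sigma_obs",
    if (use_field) c("sigma_field", "range_field"),
    if (family == "gamma") "shape"
  )
  summary_tbl <- dplyr::bind_rows(
    summarise_draws_matrix(beta_draws, colnames(X)),
    if (length(extra) > 0) {
      summarise_draws_matrix(hyper_draws[, extra, drop = FALSE], extra)
    }
  )

  structure(
    list(
      family = family,
      summary = summary_tbl,
      draws = list(beta = beta_draws, hyper = hyper_draws,
                   b = b_draws, w = w_draws),
      loglik = loglik_draws,
      accept_rate = acc / max(1, n_iter - burn),
      use_obs = use_obs, use_field = use_field,
      n_obs_levels = n_obs_levels,
      coords = coords,
      n = n, seed = seed,
      n_iter = n_iter, burn = burn, thin = thin
    ),
    class = "hurdle_stage"
  )
}

#' Fit the occurrence (presence/absence) stage
#'
#' Bernoulli likelihood with logit link over fixed effects (including the
#' year factor), an optional observer random effect and an optional Matérn
#' spatial field, sampled by a seeded adaptive Metropolis-within-Gibbs
#' scheme. Fails with an informative error when the response shows no
#' variation (all zeros or all ones).
#'
#' @param y 0/1 response per census.
#' @param design Design list from [build_design()].
#' @param coords Matrix of site coordinates (km), one row per site, or
#'   `NULL` when the spatial field is off.
#' @param site_idx Integer site index per observation (rows of `coords`).
#' @param obs_idx Integer observer index per observation, or `NULL`.
#' @param spec A [hurdle_spec()].
#' @param seed Integer seed (bit-reproducible results).
#' @param n_iter,burn,thin Sampler length, burn-in, thinning.
#' @return A `hurdle_stage` object with posterior summaries, draws and the
#'   per-observation log-likelihood matrix (draws x observations).
#' @export
fit_presence <- function(y, design, coords = NULL, site_idx = NULL,
                         obs_idx = NULL, spec = hurdle_spec(), seed = 1,
                         n_iter = 3000, burn = 1000, thin = 2) {
  fit_stage(y, design, family = "binomial", coords = coords,
            site_idx = site_idx, obs_idx = obs_idx, spec = spec,
            seed = seed, n_iter = n_iter, burn = burn, thin = thin)
}

#' Fit the positive-density stage
#'
#' Gamma likelihood with log link on the mean, fitted to the strictly
#' positive densities only, with the same random-effect structure as the
#' occurrence stage (independent parameters).
#'
#' @inheritParams fit_presence
#' @param y Strictly positive densities.
#' @return A `hurdle_stage` object.
#' @export
fit_density <- function(y, design, coords = NULL, site_idx = NULL,
                        obs_idx = NULL, spec = hurdle_spec(), seed = 1,
                        n_iter = 3000, burn = 1000, thin = 2) {
  fit_stage(y, design, family = "gamma", coords = coords,
            site_idx = site_idx, obs_idx = obs_idx, spec = spec,
            seed = seed, n_iter = n_iter, burn = burn, thin = thin)
}

#' @export
tidy.hurdle_stage <- function(x, ...) x$summary

#' Fit the two-stage hurdle spatio-temporal model
#'
#' Orchestrates the hurdle: stage 1 models presence/absence of the chosen
#' life stage per census (Bernoulli, logit link); stage 2 models the
#' strictly positive per-census densities (Gamma, log link) on the
#' presences only. Observations are put in a canonical order (site, year,
#' observer, count) before sampling so posterior summaries do not depend
#' on input row order.
#'
#' @param surveys Survey table (see [read_surveys()]).
#' @param sites Site covariate table (see [read_sites()]).
#' @param spec A [hurdle_spec()].
#' @param life_stage Which life stage to model (default `"juvenile"`).
#' @param seed Integer seed.
#' @param n_iter,burn,thin Sampler controls passed to both stages.
#' @return An object of class `hurdle_fit` holding both stage fits, the
#'   shared design metadata and the analysis data. Methods: [tidy()],
#'   [glance()], [predict_grid()], [autoplot()].
#' @export
fit_hurdle <- function(surveys, sites, spec = hurdle_spec(),
                       life_stage = "juvenile", seed = 1,
                       n_iter = 3000, burn = 1000, thin = 2) {
  validate_surveys(surveys)
  validate_sites(sites)
  df <- surveys |>
    dplyr::filter(.data$life_stage == !!life_stage) |>
    dplyr::inner_join(sites, by = "site_id") |>
    dplyr::arrange(.data$site_id, .data$year, .data$observer_id, .data$count)
  if (nrow(df) == 0) {
    stop(sprintf("no '%s' records in surveys", life_stage), call. = FALSE)
  }
  df$area_m2 <- census_area(df$radius_m)
  # continuous-mode synthetic data carry an exact density column; observed
  # data derive density from the count and census area
  if (!"density" %in% names(df)) df$density <- df$count / df$area_m2
  df$present <- as.integer(df$density > 0)
  design <- build_design(df, spec)
  site_tbl <- df |>
    dplyr::distinct(.data$site_id, .data$x_km, .data$y_km) |>
    dplyr::arrange(.data$site_id)
  coords <- as.matrix(site_tbl[, c("x_km", "y_km")])
  site_idx <- match(df$site_id, site_tbl$site_id)
  observers <- sort(unique(df$observer_id))
  obs_idx <- if (spec$observer_effect) match(df$observer_id, observers) else NULL

  stage1 <- fit_stage(
    df$present, design, family = "binomial",
    coords = if (spec$spatial_field) coords else NULL,
    site_idx = if (spec$spatial_field) site_idx else NULL,
    obs_idx = obs_idx, spec = spec, seed = seed,
    n_iter = n_iter, burn = burn, thin = thin
  )

  pos <- df$present == 1
  design_pos <- design
  design_pos$X <- design$X[pos, , drop = FALSE]
  stage2 <- fit_stage(
    df$density[pos], design_pos, family = "gamma",
    coords = if (spec$spatial_field) coords else NULL,
    site_idx = if (spec$spatial_field) site_idx[pos] else NULL,
    obs_idx = if (!is.null(obs_idx)) obs_idx[pos] else NULL,
    spec = spec, seed = seed + 1L,
    n_iter = n_iter, burn = burn, thin = thin,
    n_obs_levels = length(observers)
  )

  structure(
    list(
      binomial = stage1, gamma = stage2,
      spec = spec, design = design,
      data = df, site_tbl = site_tbl, coords = coords,
      site_idx = site_idx, observers = observers,
      life_stage = life_stage, seed = seed
    ),
    class = "hurdle_fit"
  )
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("Two-stage Bayesian hurdle model (%s)\n", x$life_stage))
  cat(sprintf("  %d censuses, %d presences, %d sites\n",
              nrow(x$data), sum(x$data$present), nrow(x$site_tbl)))
  cat("Occurrence stage (binomial):\n")
  print(x$binomial$summary, n = 6)
  cat("Density stage (Gamma):\n")
  print(x$gamma$summary, n = 6)
  invisible(x)
}

#' @export
tidy.hurdle_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$binomial$summary, stage = "binomial", .before = 1),
    dplyr::mutate(x$gamma$summary, stage = "gamma", .before = 1)
  )
}

#' @export
glance.hurdle_fit <- function(x, ...) {
  w1 <- waic(x$binomial$loglik)
  w2 <- waic(x$gamma$loglik)
  tibble::tibble(
    waic_binomial = w1$waic, waic_gamma = w2$waic,
    waic_total = w1$waic + w2$waic,
    p_waic = w1$p_waic + w2$p_waic,
    n_censuses = nrow(x$data), n_presences = sum(x$data$present)
  )
}
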