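# Bayesian latent-process Poisson trend models for yearly abundance:
# AR1, RW1 and RW2 priors on the latent log-mean trajectory, compared by
# WAIC and CPO, with low-count exclusion rules and trend-direction
# summaries.

TREND_MODELS <- c("AR1", "RW1", "RW2")

#' Aggregate census counts into yearly series
#'
#' Sums counts per year within each location (or over the whole region
#' with `group = "all"`) for one life stage, recording the number of
#' censuses per year as effort. Years with no records are simply absent
#' from a series; the latent trend process bridges such gaps.
#'
#' @param surveys Survey table.
#' @param group `"location"` for one series per location, `"all"` for a
#'   single pooled series.
#' @param life_stage Life stage to aggregate.
#' @return A tibble: `location`, `life_stage`, `year`, `count`, `effort`.
#' @export
aggregate_counts <- function(surveys, group = c("location", "all"),
                             life_stage = "juvenile") {
  group <- match.arg(group)
  df <- surveys[surveys$life_stage == life_stage, , drop = FALSE]
  if (group == "all") df$location <- "all"
  df |>
    dplyr::group_by(.data$location, .data$life_stage, .data$year) |>
    dplyr::summarise(count = sum(.data$count), effort = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$location, .data$year)
}

#' Exclusion guard for low-count series
#'
#' Marks series whose total count is below `min_total` as excluded
#' (too little signal to fit a trend) and removes explicitly listed years
#' (e.g. years with too few censuses), reporting the reason for every
#' exclusion.
#'
#' @param series Yearly count tibble from [aggregate_counts()] (one or
#'   several locations).
#' @param min_total Minimum total count for a series to be modelled
#'   (default 10).
#' @param drop_years Integer years removed from every series.
#' @return List with `series` (kept rows) and `exclusions` (tibble of
#'   `location`, `year` (NA for whole-series exclusions), `reason`).
#' @export
series_guard <- function(series, min_total = 10, drop_years = integer()) {
  stopifnot(min_total >= 0)
  exclusions <- NULL
  out <- series
  if (length(drop_years) > 0) {
    dropped <- out[out$year %in% drop_years, , drop = FALSE]
    if (nrow(dropped) > 0) {
      exclusions <- dplyr::bind_rows(
        exclusions,
        tibble::tibble(location = dropped$location, year = dropped$year,
                       reason = "year excluded by rule")
      )
    }
    out <- out[!out$year %in% drop_years, , drop = FALSE]
  }
  totals <- out |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  low <- totals$location[totals$total < min_total]
  if (length(low) > 0) {
    exclusions <- dplyr::bind_rows(
      exclusions,
      tibble::tibble(location = low, year = NA_integer_,
                     reason = "low total count")
    )
    out <- out[!out$location %in% low, , drop = FALSE]
  }
  list(series = out,
       exclusions = if (is.null(exclusions)) {
         tibble::tibble(location = character(), year = integer(),
                        reason = character())
       } else exclusions)
}

# prior quadratic form of the latent vector for each model type
latent_quadform <- function(u, type, rho = 0) {
  T <- length(u)
  switch(type,
    AR1 = (1 - rho^2) * u[1]^2 + sum((u[-1] - rho * u[-T])^2),
    RW1 = sum(diff(u)^2),
    RW2 = sum(diff(u, differences = 2)^2)
  )
}

# Per-site sums of the prior quadratic-form terms that touch each site in
# `idx`, computed from the full squared-term vector. For AR1/RW1 the t-th
# term couples sites t-1 and t; for RW2 the t-th second difference couples
# sites t-1, t, t+1. Sites at checkerboard stride (2, or 3 for RW2) share
# no term, so per-site Metropolis decisions within a class are independent.
local_quad_sites <- function(u, idx, type, rho = 0) {
  T <- length(u)
  if (type == "AR1") {
    e <- c((1 - rho^2) * u[1]^2,
           if (T > 1) (u[-1] - rho * u[-T])^2, 0)
    e[idx] + e[idx + 1]
  } else if (type == "RW1") {
    e <- c(0, diff(u)^2, 0)
    e[idx] + e[idx + 1]
  } else {
    dd <- numeric(T)
    dd[2:(T - 1)] <- diff(u, differences = 2)^2
    ddp <- c(0, dd, 0)
    ddp[idx] + ddp[idx + 1] + ddp[idx + 2]
  }
}

adapt_scale_vec <- function(s, accepted, iter, target) {
  step <- min(0.25, 5 / sqrt(iter + 10))
  pmin(1e3, pmax(1e-5, s * exp(step * (accepted - target))))
}

#' Fit a latent Poisson trend model
#'
#' Yearly counts are modelled as \eqn{y_t \sim Poisson(e^{\eta_t})} with
#' \eqn{\eta_t = \mu + u_t} and a latent prior on \eqn{u}: stationary
#' first-order autoregression (AR1), first-order random walk (RW1, favors
#' locally constant trends) or second-order random walk (RW2, favors
#' locally linear trends). Inference is a seeded Metropolis-within-Gibbs
#' sampler with conjugate Gibbs updates for the innovation precision
#' \eqn{\tau}; the latent trajectory is reported with the level centred
#' into \eqn{\mu} so RW trajectories are sum-to-zero. Gap years inside the
#' observed range are carried by the latent process and receive fitted
#' values without contributing likelihood.
#'
#' @param series Single-location tibble with `year` and `count` columns.
#' @param model `"AR1"`, `"RW1"` or `"RW2"`.
#' @param seed Integer seed.
#' @param n_iter,burn,thin Sampler controls.
#' @return Object of class `trend_fit`: posterior draws of the latent
#'   trajectory and hyperparameters, a fitted tibble (`year`, `post_mean`,
#'   `q2.5`, `q97.5` on the count scale), `waic` and `lcpo`.
#' @export
fit_trend <- function(series, model = c("AR1", "RW1", "RW2"), seed = 1,
                      n_iter = 4000, burn = 1500, thin = 2) {
  model <- match.arg(model)
  if (length(unique(series$location)) > 1) {
    stop("`series` must contain a single location; map over groups instead.",
         call. = FALSE)
  }
  series <- dplyr::arrange(series, .data$year)
  years_obs <- series$year
  y <- series$count
  min_T <- if (model == "RW2") 4 else 3
  if (length(y) < min_T) {
    stop(sprintf("%s needs at least %d observed years (got %d).",
                 model, min_T, length(y)), call. = FALSE)
  }
  years_all <- seq(min(years_obs), max(years_obs))
  T <- length(years_all)
  obs_at <- match(years_obs, years_all)
  y_full <- rep(NA_real_, T)
  y_full[obs_at] <- y
  observed <- !is.na(y_full)

  set.seed(seed)
  # prior constants
  mu_sd <- 10          # N(0, 100) on the intercept
  tau_a <- 1; tau_b <- 0.01   # vague Gamma on the innovation precision
  # logit((rho+1)/2) prior: the conventional vague precision 0.15
  # (sd ~ 2.58); a standard-normal prior here visibly shrinks rho toward 0
  # on series of 20-30 years
  rho_prior_sd <- sqrt(1 / 0.15)

  mu <- log(mean(y) + 0.5)
  u <- rep(0, T)
  u[observed] <- log(y + 0.5) - mu
  # linear interpolation for latent values at gap years
  if (any(!observed)) {
    u[!observed] <- stats::approx(which(observed), u[observed],
                                  xout = which(!observed), rule = 2)$y
  }
  tau <- 4
  rho <- 0.5
  s_u <- rep(0.3, T)
  s_mu <- 0.2
  s_rho <- 0.5
  s_rho_nc <- 0.5
  s_shift <- 0.3

  rank_def <- switch(model, AR1 = 0L, RW1 = 1L, RW2 = 2L)
  stride <- if (model == "RW2") 3L else 2L
  classes <- lapply(seq_len(stride), function(k) seq(k, T, by = stride))
  y0 <- ifelse(observed, y_full, 0)   # unobserved years add no likelihood

  n_save <- floor((n_iter - burn) / thin)
  eta_draws <- matrix(NA_real_, n_save, T)
  hyper_draws <- matrix(NA_real_, n_save, 3,
                        dimnames = list(NULL, c("tau", "rho", "mu")))
  loglik_draws <- matrix(NA_real_, n_save, sum(observed))
  save_i <- 0L

  for (it in seq_len(n_iter)) {
    ## latent updates, one checkerboard class at a time (vectorized)
    for (idx in classes) {
      q_cur <- local_quad_sites(u, idx, model, rho)
      prop <- u[idx] + s_u[idx] * stats::rnorm(length(idx))
      u_prop <- u
      u_prop[idx] <- prop
      q_new <- local_quad_sites(u_prop, idx, model, rho)
      ll_cur <- ifelse(observed[idx],
                       y0[idx] * (mu + u[idx]) - exp(mu + u[idx]), 0)
      ll_new <- ifelse(observed[idx],
                       y0[idx] * (mu + prop) - exp(mu + prop), 0)
      logacc <- ll_new - ll_cur - 0.5 * tau * (q_new - q_cur)
      acc <- log(stats::runif(length(idx))) < logacc
      u[idx[acc]] <- prop[acc]
      s_u[idx] <- adapt_scale_vec(s_u[idx], as.numeric(acc), it, 0.44)
    }

    ## intercept (random-walk MH on mu)
    mu_p <- mu + s_mu * stats::rnorm(1)
    d <- sum(y_full[observed] * (mu_p + u[observed]) -
               exp(mu_p + u[observed])) -
      sum(y_full[observed] * (mu + u[observed]) - exp(mu + u[observed])) +
      stats::dnorm(mu_p, 0, mu_sd, log = TRUE) -
      stats::dnorm(mu, 0, mu_sd, log = TRUE)
    acc <- log(stats::runif(1)) < d
    if (acc) mu <- mu_p
    s_mu <- adapt_scale(s_mu, as.numeric(acc), it, 0.44)

    ## level-swap move: shifts level between mu and u, likelihood-invariant
    delta <- s_shift * stats::rnorm(1)
    mu_p <- mu + delta
    u_p <- u - delta
    d <- -0.5 * tau * (latent_quadform(u_p, model, rho) -
                         latent_quadform(u, model, rho)) +
      stats::dnorm(mu_p, 0, mu_sd, log = TRUE) -
      stats::dnorm(mu, 0, mu_sd, log = TRUE)
    acc <- log(stats::runif(1)) < d
    if (acc) {
      mu <- mu_p; u <- u_p
    }
    s_shift <- adapt_scale(s_shift, as.numeric(acc), it, 0.44)

    ## global slope move for RW2 (prior-invariant direction)
    if (model == "RW2") {
      gam <- 0.05 * stats::rnorm(1)
      tt <- seq_len(T) - mean(seq_len(T))
      u_p <- u + gam * tt
      d <- sum(y_full[observed] * (mu + u_p[observed]) -
                 exp(mu + u_p[observed])) -
        sum(y_full[observed] * (mu + u[observed]) - exp(mu + u[observed]))
      if (log(stats::runif(1)) < d) u <- u_p
    }

    ## innovation precision: conjugate Gibbs
    q <- latent_quadform(u, model, rho)
    tau <- stats::rgamma(1, tau_a + (T - rank_def) / 2, rate = tau_b + q / 2)

    ## AR1 correlation: centered update (u fixed) ...
    if (model == "AR1") {
      theta <- stats::qlogis((rho + 1) / 2)
      theta_p <- theta + s_rho * stats::rnorm(1)
      rho_p <- 2 * stats::plogis(theta_p) - 1
      logdens <- function(r, th) {
        0.5 * log(1 - r^2) - 0.5 * tau * latent_quadform(u, "AR1", r) +
          stats::dnorm(th, 0, rho_prior_sd, log = TRUE) +
          log((1 - r^2) / 2)
      }
      d <- logdens(rho_p, theta_p) - logdens(rho, theta)
      acc <- log(stats::runif(1)) < d
      if (acc) rho <- rho_p
      s_rho <- adapt_scale(s_rho, as.numeric(acc), it, 0.44)

      ## ... interleaved with a non-centered move: hold the innovations
      ## fixed and rebuild u under the proposed rho, which breaks the
      ## strong u-rho coupling of the centered step
      eps <- c(u[1] * sqrt(1 - rho^2), if (T > 1) u[-1] - rho * u[-T])
      theta <- stats::qlogis((rho + 1) / 2)
      theta_p <- theta + s_rho_nc * stats::rnorm(1)
      rho_p <- 2 * stats::plogis(theta_p) - 1
      u_p <- numeric(T)
      u_p[1] <- eps[1] / sqrt(1 - rho_p^2)
      for (t in seq_len(T - 1) + 1) u_p[t] <- rho_p * u_p[t - 1] + eps[t]
      d <- sum(y0[observed] * (mu + u_p[observed]) -
                 exp(mu + u_p[observed])) -
        sum(y0[observed] * (mu + u[observed]) - exp(mu + u[observed])) +
        stats::dnorm(theta_p, 0, rho_prior_sd, log = TRUE) -
        stats::dnorm(theta, 0, rho_prior_sd, log = TRUE)
      acc <- log(stats::runif(1)) < d
      if (acc) {
        rho <- rho_p
        u <- u_p
      }
      s_rho_nc <- adapt_scale(s_rho_nc, as.numeric(acc), it, 0.44)
    }

    if (it > burn && (it - burn) %% thin == 0) {
      save_i <- save_i + 1L
      # report with the RW level centred into mu (sum-to-zero trajectory)
      ctr <- if (model == "AR1") 0 else mean(u)
      eta_draws[save_i, ] <- (mu + ctr) + (u - ctr)
      hyper_draws[save_i, ] <- c(tau, if (model == "AR1") rho else NA_real_,
                                 mu + ctr)
      eta_obs <- mu + u[observed]
      loglik_draws[save_i, ] <- stats::dpois(y_full[observed], exp(eta_obs),
                                             log = TRUE)
    }
  }

  fitted_mean <- colMeans(exp(eta_draws))
  qs <- apply(exp(eta_draws), 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  fitted <- tibble::tibble(
    year = years_all,
    post_mean = fitted_mean,
    q2.5 = qs[1, ], q97.5 = qs[2, ],
    observed = observed,
    count = y_full
  )
  w <- waic(loglik_draws)
  cp <- cpo(loglik_draws)
  structure(
    list(
      model = model,
      location = series$location[1],
      life_stage = if ("life_stage" %in% names(series))
        series$life_stage[1] else NA_character_,
      years = years_all, observed = observed,
      eta_draws = eta_draws, hyper_draws = hyper_draws,
      loglik = loglik_draws,
      fitted = fitted,
      waic = w$waic, p_waic = w$p_waic, lcpo = cp$lcpo,
      seed = seed
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Latent Poisson %s trend (%s), %d years\n",
              x$model, x$location, length(x$years)))
  cat(sprintf("  WAIC = %.2f (p = %.2f), LCPO = %.3f\n",
              x$waic, x$p_waic, x$lcpo))
  print(x$fitted)
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) x$fitted

#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(model = x$model, location = x$location,
                 waic = x$waic, p_waic = x$p_waic, lcpo = x$lcpo,
                 n_years = sum(x$observed))
}

#' Fit and rank the three trend models
#'
#' Fits AR1, RW1 and RW2 (where the series is long enough) and ranks them
#' on the compromise of low WAIC and low LCPO (rank sum). The final choice
#' is the best *and most parsimonious* model: when a model with fewer
#' hyperparameters sits within `parsimony_margin` WAIC units of the
#' rank-sum winner (the conventional practical-equivalence margin of 2),
#' the simpler model is preferred. RW1 (one hyperparameter) counts as
#' simpler than AR1 and RW2. Exact rank ties also resolve toward the
#' simpler model, then lower WAIC.
#'
#' @inheritParams fit_trend
#' @param parsimony_margin WAIC margin within which a simpler model
#'   supersedes the rank-sum winner; 0 disables the preference.
#' @return Object of class `trend_comparison`: list with `fits`, the
#'   ranking `table`, and the `chosen` model name.
#' @export
compare_trends <- function(series, seed = 1, n_iter = 4000, burn = 1500,
                           thin = 2, parsimony_margin = 2) {
  models <- TREND_MODELS
  n_obs <- nrow(series)
  if (n_obs < 4) models <- setdiff(models, "RW2")
  if (n_obs < 3) stop("series too short for any trend model.", call. = FALSE)
  fits <- lapply(stats::setNames(models, models), function(m) {
    fit_trend(series, m, seed = seed, n_iter = n_iter, burn = burn,
              thin = thin)
  })
  tbl <- purrr::map_dfr(fits, glance)
  rank_sum <- rank(tbl$waic) + rank(tbl$lcpo)
  # tie-break preference order: RW1 (fewest hyperparameters), then by WAIC
  complexity <- c(RW1 = 1, AR1 = 2, RW2 = 2)[tbl$model]
  ord <- order(rank_sum, complexity, tbl$waic)
  winner <- ord[1]
  # parsimony: a simpler model practically equivalent in WAIC supersedes
  simpler <- which(complexity < complexity[winner] &
                     tbl$waic <= tbl$waic[winner] + parsimony_margin)
  if (length(simpler) > 0) {
    winner <- simpler[order(complexity[simpler], tbl$waic[simpler])][1]
  }
  tbl$rank_sum <- rank_sum
  tbl$chosen <- seq_len(nrow(tbl)) == winner
  structure(
    list(fits = fits, table = tbl, chosen = tbl$model[winner]),
    class = "trend_comparison"
  )
}

#' @export
print.trend_comparison <- function(x, ...) {
  cat("Trend model comparison (WAIC + LCPO rank sum)\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.trend_comparison <- function(x, ...) x$table

#' Posterior direction of a fitted trend
#'
#' Classifies the change of the latent log-mean between two fitted years
#' from its posterior: declining when the posterior probability that
#' \eqn{\eta_{to} < \eta_{from}} reaches `declining_prob`,
#' increasing when it falls below `increasing_prob`, flat otherwise.
#'
#' @param fit A [fit_trend()] object.
#' @param from_year,to_year Years inside the fitted range.
#' @param declining_prob,increasing_prob Classification thresholds.
#' @return One-row tibble: `from_year`, `to_year`, `direction`,
#'   `prob_decline`.
#' @export
trend_direction <- function(fit, from_year = NULL, to_year = NULL,
                            declining_prob = 0.9, increasing_prob = 0.1) {
  if (is.null(from_year)) from_year <- min(fit$years)
  if (is.null(to_year)) to_year <- max(fit$years)
  i <- match(from_year, fit$years)
  j <- match(to_year, fit$years)
  if (is.na(i) || is.na(j)) {
    stop(sprintf("years must lie in the fitted range %d-%d.",
                 min(fit$years), max(fit$years)), call. = FALSE)
  }
  p_dec <- mean(fit$eta_draws[, j] < fit$eta_draws[, i])
  direction <- if (p_dec >= declining_prob) "declining"
  else if (p_dec <= increasing_prob) "increasing"
  else "flat"
  tibble::tibble(from_year = from_year, to_year = to_year,
                 direction = direction, prob_decline = p_dec)
}
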