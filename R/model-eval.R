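# Model evaluation: WAIC, CPO, prediction metrics, the three-criterion
# backward variable-selection loop, and repeated split-half cross-validation.

log_mean_exp_cols <- function(m) {
  # column-wise log(mean(exp(x))) computed stably
  mx <- apply(m, 2, max)
  mx + log(colMeans(exp(sweep(m, 2, mx))))
}

#' Watanabe-Akaike information criterion
#'
#' Computed from a matrix of per-observation posterior log-likelihood
#' draws: \deqn{WAIC = -2 \sum_i \left[\log \tfrac1S \sum_s e^{\ell_{si}}
#' - \mathrm{Var}_s(\ell_{si})\right]} with the effective parameter count
#' \eqn{p_{WAIC} = \sum_i \mathrm{Var}_s(\ell_{si})}. Lower is better.
#'
#' @param loglik Numeric matrix, draws (rows) by observations (columns).
#' @return List with `waic`, `p_waic`, `lppd`, and the per-observation
#'   `pointwise` tibble.
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) {
    stop("WAIC needs at least 2 posterior draws (variance undefined).",
         call. = FALSE)
  }
  if (any(!is.finite(loglik))) {
    stop("log-likelihood matrix contains non-finite values.", call. = FALSE)
  }
  lppd_i <- log_mean_exp_cols(loglik)
  p_i <- apply(loglik, 2, stats::var)
  list(
    waic = -2 * (sum(lppd_i) - sum(p_i)),
    p_waic = sum(p_i),
    lppd = sum(lppd_i),
    pointwise = tibble::tibble(lppd = lppd_i, p_waic = p_i,
                               waic = -2 * (lppd_i - p_i))
  )
}

#' Conditional predictive ordinates
#'
#' Leave-one-out predictive density of each observation via the
#' harmonic-mean identity \eqn{CPO_i = [\frac1S \sum_s e^{-\ell_{si}}]^{-1}},
#' overflow-guarded through log-sum-exp, and the smaller-is-better summary
#' \eqn{LCPO = -\frac1n \sum_i \log CPO_i}.
#'
#' @inheritParams waic
#' @return List with per-observation `cpo` and the `lcpo` summary.
#' @export
cpo <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) {
    stop("CPO needs at least 2 posterior draws.", call. = FALSE)
  }
  if (any(!is.finite(loglik))) {
    stop("log-likelihood matrix contains non-finite values.", call. = FALSE)
  }
  log_inv_cpo <- log_mean_exp_cols(-loglik)
  list(cpo = exp(-log_inv_cpo), lcpo = mean(log_inv_cpo))
}

#' Prediction-skill metrics
#'
#' Root-mean-square error, Pearson correlation, its square (the
#' coefficient of determination of observed against predicted), and the
#' average error (mean absolute error).
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2);
#'   `observed` must not be constant (correlation undefined).
#' @return A one-row tibble: `rmse`, `pearson_r`, `r2`, `ave_error`, `n`.
#' @export
prediction_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("`observed` and `predicted` must have equal length >= 2.",
         call. = FALSE)
  }
  if (stats::sd(observed) == 0) {
    stop("`observed` is constant; correlation is undefined.", call. = FALSE)
  }
  r <- stats::cor(observed, predicted)
  tibble::tibble(
    rmse = sqrt(mean((observed - predicted)^2)),
    pearson_r = r,
    r2 = r^2,
    ave_error = mean(abs(observed - predicted)),
    n = length(observed)
  )
}

# Relevance of a covariate term: largest |mean|/sd over the two stages,
# and whether any stage's 95% CI excludes zero.
term_relevance <- function(fit, terms) {
  tdy <- tidy(fit)
  purrr::map_dfr(terms, function(tm) {
    rows <- tdy[tdy$term == tm, ]
    tibble::tibble(
      term = tm,
      z = max(abs(rows$estimate) / pmax(rows$std.error, 1e-12)),
      relevant = any(rows$conf.low > 0 | rows$conf.high < 0)
    )
  })
}

score_spec <- function(fit) {
  w <- waic(fit$binomial$loglik)$waic + waic(fit$gamma$loglik)$waic
  pred <- predict_hurdle_rows(fit)
  m <- prediction_metrics(fit$data$density, pred$expected_density)
  tibble::tibble(waic = w, rmse = m$rmse, r2 = m$r2)
}

#' Backward variable selection for the hurdle model
#'
#' Starting from the full main-effects specification (plus any declared
#' interactions), iteratively refits the hurdle model and drops the
#' predictor whose 95% credible interval most widely covers zero in both
#' stages (smallest max-over-stages |posterior mean| / sd), until every
#' remaining predictor has a 95% interval excluding zero in at least one
#' stage. Visited specifications are then ranked on the compromise of low
#' WAIC, low RMSE and high R\eqn{^2} (rank sum; ties broken by fewer terms,
#' then lower WAIC).
#'
#' @param surveys,sites Survey and site tables.
#' @param spec Starting [hurdle_spec()].
#' @param seed Integer seed used for every refit.
#' @param life_stage Life stage modelled.
#' @param n_iter,burn,thin Sampler controls per refit.
#' @param max_steps Safety cap on elimination steps.
#' @return Object of class `model_selection`: list with `spec` (chosen),
#'   `fit` (refit of the chosen spec), `scores` (one row per visited spec),
#'   and `all_relevant` (FALSE sets a warning flag when no visited spec had
#'   only relevant predictors).
#' @export
select_model <- function(surveys, sites, spec = hurdle_spec(), seed = 1,
                         life_stage = "juvenile",
                         n_iter = 1500, burn = 500, thin = 2,
                         max_steps = 25) {
  current <- spec
  visited <- list()
  scores <- NULL
  step <- 0
  repeat {
    step <- step + 1
    fit <- fit_hurdle(surveys, sites, current, life_stage = life_stage,
                      seed = seed, n_iter = n_iter, burn = burn, thin = thin)
    cov_terms <- c(current$terms, current$interactions)
    rel <- if (length(cov_terms) > 0) term_relevance(fit, cov_terms) else
      tibble::tibble(term = character(), z = numeric(), relevant = logical())
    sc <- score_spec(fit)
    spec_id <- paste(cov_terms, collapse = "+")
    visited[[length(visited) + 1]] <- list(spec = current, fit = fit)
    scores <- dplyr::bind_rows(scores, dplyr::mutate(
      sc,
      spec_id = if (spec_id == "") "(intercept)" else spec_id,
      n_terms = length(cov_terms),
      all_relevant = all(rel$relevant),
      .before = 1
    ))
    if (all(rel$relevant) || length(cov_terms) == 0 || step >= max_steps) break
    drop_term <- rel$term[rel$relevant == FALSE][
      which.min(rel$z[rel$relevant == FALSE])]
    # dropping a main effect removes interactions that mention it
    if (drop_term %in% current$interactions) {
      current$interactions <- setdiff(current$interactions, drop_term)
    } else {
      current$terms <- setdiff(current$terms, drop_term)
      keep_ia <- !vapply(strsplit(current$interactions, ":", fixed = TRUE),
                         function(p) drop_term %in% p, logical(1))
      current$interactions <- current$interactions[keep_ia]
    }
  }
  candidates <- if (any(scores$all_relevant)) which(scores$all_relevant)
  else seq_len(nrow(scores))
  rank_sum <- rank(scores$waic[candidates]) +
    rank(scores$rmse[candidates]) +
    rank(-scores$r2[candidates])
  best_pool <- candidates[rank_sum == min(rank_sum)]
  best <- best_pool[order(scores$n_terms[best_pool],
                          scores$waic[best_pool])][1]
  scores$rank_sum <- NA_real_
  scores$rank_sum[candidates] <- rank_sum
  scores$chosen <- seq_len(nrow(scores)) == best
  structure(
    list(
      spec = visited[[best]]$spec,
      fit = visited[[best]]$fit,
      scores = scores,
      all_relevant = any(scores$all_relevant)
    ),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Hurdle-model backward selection\n")
  print(x$scores)
  if (!x$all_relevant) {
    cat("warning: no visited specification had all predictors' 95% CIs excluding zero\n")
  }
  invisible(x)
}

#' @export
tidy.model_selection <- function(x, ...) x$scores

#' Repeated split-half cross-validation of the hurdle model
#'
#' Repeats `folds` times: a seeded random split assigns a fraction
#' `split_fraction` of censuses to training; the hurdle model is refitted
#' on the training half and the expected density predicted for the
#' held-out half; Pearson's r and the average error (mean absolute error)
#' are computed per repeat and pooled over all held-out predictions.
#' Degenerate training halves (no presence or no absence) are redrawn a
#' bounded number of times.
#'
#' @inheritParams select_model
#' @param folds Number of repeated splits (default 10).
#' @param split_fraction Training fraction (default 0.5).
#' @param max_retries Redraws allowed per fold for degenerate splits.
#' @return Object of class `cv_report`: list with per-fold tibble `folds`,
#'   pooled `pearson_r` and `ave_error`, and the split settings.
#' @export
cross_validate <- function(surveys, sites, spec = hurdle_spec(),
                           folds = 10, split_fraction = 0.5, seed = 1,
                           life_stage = "juvenile",
                           n_iter = 1500, burn = 500, thin = 2,
                           max_retries = 20) {
  validate_surveys(surveys)
  stage_rows <- which(surveys$life_stage == life_stage)
  n <- length(stage_rows)
  if (n < 4) stop("too few censuses to split.", call. = FALSE)
  set.seed(seed)
  fold_tbl <- NULL
  pooled_obs <- numeric(0)
  pooled_pred <- numeric(0)
  for (k in seq_len(folds)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      train_local <- sample.int(n, floor(split_fraction * n))
      train_idx <- stage_rows[train_local]
      test_idx <- stage_rows[-train_local]
      counts_train <- surveys$count[train_idx]
      if (any(counts_train > 0) && any(counts_train == 0) &&
          sum(counts_train > 0) >= 3) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "could not draw a usable training split after %d retries (fold %d).",
        max_retries, k), call. = FALSE)
    }
    fit <- fit_hurdle(surveys[train_idx, , drop = FALSE], sites, spec,
                      life_stage = life_stage, seed = seed + k,
                      n_iter = n_iter, burn = burn, thin = thin)
    held <- surveys[test_idx, , drop = FALSE] |>
      dplyr::inner_join(sites, by = "site_id")
    if (!"density" %in% names(held)) {
      held$density <- held$count / census_area(held$radius_m)
    }
    pred <- predict_hurdle_rows(fit, held)
    m <- prediction_metrics(held$density, pred$expected_density)
    fold_tbl <- dplyr::bind_rows(fold_tbl,
                                 dplyr::mutate(m, fold = k, .before = 1))
    pooled_obs <- c(pooled_obs, held$density)
    pooled_pred <- c(pooled_pred, pred$expected_density)
  }
  pooled <- prediction_metrics(pooled_obs, pooled_pred)
  structure(
    list(
      folds = fold_tbl,
      pearson_r = pooled$pearson_r,
      ave_error = pooled$ave_error,
      rmse = pooled$rmse,
      n_folds = folds, split_fraction = split_fraction, seed = seed
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "Split-half cross-validation: %d repeats, training fraction %.2f\n",
    x$n_folds, x$split_fraction))
  cat(sprintf("  pooled Pearson r = %.3f, AVEerror = %.4f\n",
              x$pearson_r, x$ave_error))
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, ave_error = x$ave_error,
                 rmse = x$rmse, folds = x$n_folds,
                 split_fraction = x$split_fraction)
}
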