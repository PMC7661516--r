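# Grid prediction for the fitted hurdle model: per-cell posterior-mean
# presence probability, conditional density and combined expected density,
# with the spatial field interpolated to cells by its conditional mean.

# Kriging weight matrix: E[w(cells) | w(sites)] = C_cs C_ss^{-1} w(sites),
# built from posterior-mean field hyperparameters of one stage.
krige_weights <- function(stage, new_coords) {
  if (!stage$use_field) return(NULL)
  sig <- mean(stage$draws$hyper[, "sigma_field"])
  rng <- mean(stage$draws$hyper[, "range_field"])
  site_coords <- stage$coords
  Css <- matern_cov_matrix(site_coords, sig, rng)
  d_cs <- sqrt(outer(new_coords[, 1], site_coords[, 1], "-")^2 +
                 outer(new_coords[, 2], site_coords[, 2], "-")^2)
  Ccs <- matrix(matern_cov(d_cs, sig, rng), nrow = nrow(new_coords))
  Ccs %*% chol2inv(chol(Css))
}

# Linear-predictor draws at new rows: draws x rows matrix.
stage_linpred_draws <- function(stage, X_new, krige_W = NULL,
                                site_idx_new = NULL, obs_idx_new = NULL) {
  eta <- stage$draws$beta %*% t(X_new)
  if (stage$use_field) {
    if (!is.null(site_idx_new)) {
      eta <- eta + stage$draws$w[, site_idx_new, drop = FALSE]
    } else if (!is.null(krige_W)) {
      eta <- eta + stage$draws$w %*% t(krige_W)
    }
  }
  if (stage$use_obs && !is.null(obs_idx_new)) {
    known <- !is.na(obs_idx_new)
    if (any(known)) {
      add <- matrix(0, nrow(eta), length(obs_idx_new))
      add[, known] <- stage$draws$b[, obs_idx_new[known], drop = FALSE]
      eta <- eta + add
    }
  }
  eta
}

# Per-observation (or new-row) hurdle predictions. For observer effects,
# unknown observers contribute zero (population-level prediction).
predict_hurdle_rows <- function(fit, newdata = NULL, marginal_year = FALSE) {
  if (is.null(newdata)) newdata <- fit$data
  design_new <- build_design(newdata, fit$spec,
                             scaling = fit$design$scaling,
                             year_levels = fit$design$year_levels)
  X <- design_new$X
  if (marginal_year && fit$spec$year_factor) {
    yr_cols <- grep("^year", colnames(X))
    n_years <- length(fit$design$year_levels)
    X[, yr_cols] <- 1 / n_years
  }
  # site match: exact site reuse where possible, kriging otherwise
  site_idx_new <- if ("site_id" %in% names(newdata)) {
    match(newdata$site_id, fit$site_tbl$site_id)
  } else {
    rep(NA_integer_, nrow(newdata))
  }
  obs_idx_new <- if ("observer_id" %in% names(newdata)) {
    match(newdata$observer_id, fit$observers)
  } else {
    rep(NA_integer_, nrow(newdata))
  }
  use_site <- !anyNA(site_idx_new)
  if (!use_site && fit$binomial$use_field) {
    coords_new <- as.matrix(newdata[, c("x_km", "y_km")])
    kW1 <- krige_weights(fit$binomial, coords_new)
    kW2 <- krige_weights(fit$gamma, coords_new)
  } else {
    kW1 <- kW2 <- NULL
  }
  eta1 <- stage_linpred_draws(fit$binomial, X,
                              krige_W = kW1,
                              site_idx_new = if (use_site) site_idx_new,
                              obs_idx_new = obs_idx_new)
  eta2 <- stage_linpred_draws(fit$gamma, X,
                              krige_W = kW2,
                              site_idx_new = if (use_site) site_idx_new,
                              obs_idx_new = obs_idx_new)
  p <- colMeans(stats::plogis(eta1))
  mu <- colMeans(exp(eta2))
  tibble::tibble(p_presence = p, mu_conditional = mu,
                 expected_density = p * mu)
}

#' Predict the hurdle model on a spatial grid
#'
#' Per grid cell, the posterior-mean presence probability (stage 1), the
#' posterior-mean conditional density (stage 2), and their product, the
#' expected density of the delta (hurdle) model. The spatial field is
#' interpolated to cells by its conditional (kriging) mean under the
#' Matérn covariance with posterior-mean hyperparameters; observer effects
#' are marginalised to zero. `mode = "per-year"` returns one layer per
#' fitted year (year-factor effect applied); `mode = "period-mean"`
#' averages the year effects, matching a prediction from period-mean
#' covariates. Cells with a missing covariate are flagged and left `NA`,
#' never imputed.
#'
#' @param fit A [fit_hurdle()] object.
#' @param grid Data frame of cells: `x_km`, `y_km` plus every covariate the
#'   spec uses.
#' @param mode `"period-mean"` (default) or `"per-year"`.
#' @return A tibble: the grid columns plus (`year`,) `p_presence`,
#'   `mu_conditional`, `expected_density`, `missing`.
#' @export
predict_grid <- function(fit, grid, mode = c("period-mean", "per-year")) {
  mode <- match.arg(mode)
  need <- fit$spec$terms
  miss_any <- rep(FALSE, nrow(grid))
  for (tm in need) {
    if (!tm %in% names(grid)) {
      stop(sprintf("grid is missing covariate column '%s'", tm),
           call. = FALSE)
    }
    miss_any <- miss_any | is.na(grid[[tm]])
  }
  complete <- !miss_any
  if (!any(complete)) stop("every grid cell has missing covariates.",
                           call. = FALSE)
  grid_ok <- grid[complete, , drop = FALSE]
  years <- fit$design$year_levels
  predict_one <- function(gdat, marginal_year) {
    predict_hurdle_rows(fit, gdat, marginal_year = marginal_year)
  }
  if (mode == "period-mean") {
    preds <- predict_one(dplyr::mutate(grid_ok, year = years[1]),
                         marginal_year = TRUE)
    out <- dplyr::bind_cols(grid_ok, preds)
    out$missing <- FALSE
    if (any(!complete)) {
      miss <- grid[!complete, , drop = FALSE]
      miss$p_presence <- NA_real_
      miss$mu_conditional <- NA_real_
      miss$expected_density <- NA_real_
      miss$missing <- TRUE
      out <- dplyr::bind_rows(out, miss)
    }
  } else {
    out <- purrr::map_dfr(years, function(yr) {
      gdat <- dplyr::mutate(grid_ok, year = yr)
      res <- dplyr::bind_cols(gdat, predict_one(gdat, marginal_year = FALSE))
      res$missing <- FALSE
      res
    })
    if (any(!complete)) {
      miss <- purrr::map_dfr(years, function(yr) {
        m <- dplyr::mutate(grid[!complete, , drop = FALSE], year = yr)
        m$p_presence <- NA_real_
        m$mu_conditional <- NA_real_
        m$expected_density <- NA_real_
        m$missing <- TRUE
        m
      })
      out <- dplyr::bind_rows(out, miss)
    }
  }
  class(out) <- c("prediction_grid", class(out))
  out
}

#' Flag hotspot (nursery candidate) cells
#'
#' Marks cells whose expected density reaches the empirical `q`-quantile of
#' all non-missing cells; ties at the threshold are kept, so a constant
#' grid is flagged in full.
#'
#' @param grid A [predict_grid()] result (or any data frame with an
#'   `expected_density` column).
#' @param q Quantile in (0, 1); default 0.9 keeps the top decile.
#' @return The input with a logical `hotspot` column.
#' @export
hotspot_cells <- function(grid, q = 0.9) {
  if (!(q > 0 && q < 1)) stop("`q` must lie strictly in (0, 1).",
                              call. = FALSE)
  vals <- grid$expected_density
  ok <- !is.na(vals)
  if (!any(ok)) stop("all cells are missing; no hotspot threshold exists.",
                     call. = FALSE)
  thr <- stats::quantile(vals[ok], q, names = FALSE)
  grid$hotspot <- !is.na(vals) & vals >= thr
  grid
}
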