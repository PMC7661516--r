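# Model specification for the two-stage hurdle spatio-temporal model.

#' Specify a hurdle spatio-temporal model
#'
#' Describes the linear predictor shared (structurally) by the two hurdle
#' stages: covariate main effects, optional pairwise interactions, an
#' observer random effect, a year factor (first year as reference) and a
#' Matérn spatial random field. Fixed effects get vague Normal(0, 100)
#' priors (sd 10). Hyperpriors follow weakly-informative defaults:
#' half-Normal(0, 2\eqn{^2}) on the observer and field standard deviations,
#' log-Normal(log 20, 1) on the field range (km), Gamma(2, 0.5) on the
#' Gamma-stage shape.
#'
#' @param terms Character vector of covariate column names (main effects).
#' @param interactions Character vector of `"a:b"` pairwise interactions.
#' @param observer_effect,year_factor,spatial_field Logical switches for the
#'   random-effect structure.
#' @param prior_fixed_sd Prior standard deviation of fixed effects
#'   (default `sqrt(100)`).
#' @param hyper Named list of hyperprior parameters; see Details.
#' @return Object of class `hurdle_spec`.
#' @export
hurdle_spec <- function(terms = c(BENTHIC_COVARIATES, ENVIRONMENTAL_COVARIATES),
                        interactions = character(),
                        observer_effect = TRUE,
                        year_factor = TRUE,
                        spatial_field = TRUE,
                        prior_fixed_sd = 10,
                        hyper = list()) {
  default_hyper <- list(
    obs_sd_scale = 2,      # half-Normal scale for observer sd
    field_sd_scale = 2,    # half-Normal scale for field marginal sd
    range_meanlog = log(20), range_sdlog = 1,  # log-Normal on range (km)
    shape_shape = 2, shape_rate = 0.5          # Gamma prior on Gamma shape
  )
  hyper <- utils::modifyList(default_hyper, hyper)
  bad <- setdiff(unlist(strsplit(interactions, ":", fixed = TRUE)), terms)
  if (length(bad) > 0) {
    stop(sprintf("interaction references unknown term(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  structure(
    list(
      terms = terms, interactions = interactions,
      observer_effect = isTRUE(observer_effect),
      year_factor = isTRUE(year_factor),
      spatial_field = isTRUE(spatial_field),
      prior_fixed_sd = prior_fixed_sd,
      hyper = hyper
    ),
    class = "hurdle_spec"
  )
}

#' @export
print.hurdle_spec <- function(x, ...) {
  cat("Hurdle model specification\n")
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = ", ")
      else "(intercept only)", "\n")
  if (length(x$interactions))
    cat("  interactions:", paste(x$interactions, collapse = ", "), "\n")
  cat(sprintf("  observer effect: %s, year factor: %s, spatial field: %s\n",
              x$observer_effect, x$year_factor, x$spatial_field))
  invisible(x)
}

#' Build design matrices for a hurdle stage
#'
#' Expands a specification against observation-level covariate data.
#' Continuous covariates are centred and scaled by training-set statistics
#' (stored and reused for prediction); binary 0/1 covariates are left
#' untouched; interaction columns are elementwise products of the
#' standardized main-effect columns; the year factor is dummy-coded with
#' the first year as reference.
#'
#' @param data Data frame with one row per observation, containing every
#'   covariate named in the spec and, when used, `year`.
#' @param spec A [hurdle_spec()].
#' @param scaling Optional scaling list from a previous call (training
#'   transform reused on new data).
#' @param year_levels Optional fixed year levels (training years).
#' @return List with the model matrix `X`, `scaling`, `year_levels`, and
#'   `term_cols` (term name to column index map).
#' @export
build_design <- function(data, spec, scaling = NULL, year_levels = NULL) {
  n <- nrow(data)
  for (tm in spec$terms) {
    if (!tm %in% names(data)) {
      stop(sprintf("covariate '%s' not found in data", tm), call. = FALSE)
    }
    if (anyNA(data[[tm]])) {
      bad_row <- which(is.na(data[[tm]]))[1]
      site <- if ("site_id" %in% names(data)) data$site_id[bad_row] else bad_row
      stop(sprintf("missing value for covariate '%s' (site %s)", tm, site),
           call. = FALSE)
    }
  }
  if (is.null(scaling)) {
    scaling <- lapply(stats::setNames(spec$terms, spec$terms), function(tm) {
      x <- data[[tm]]
      if (all(x %in% c(0, 1))) {
        list(center = 0, scale = 1, binary = TRUE)
      } else {
        s <- stats::sd(x)
        list(center = mean(x), scale = if (s > 0) s else 1, binary = FALSE)
      }
    })
  }
  std_col <- function(tm) {
    (data[[tm]] - scaling[[tm]]$center) / scaling[[tm]]$scale
  }
  cols <- list(`(Intercept)` = rep(1, n))
  term_cols <- list(`(Intercept)` = 1L)
  k <- 1L
  for (tm in spec$terms) {
    cols[[tm]] <- std_col(tm)
    k <- k + 1L
    term_cols[[tm]] <- k
  }
  for (ia in spec$interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    cols[[ia]] <- std_col(parts[1]) * std_col(parts[2])
    k <- k + 1L
    term_cols[[ia]] <- k
  }
  if (spec$year_factor) {
    if (!"year" %in% names(data)) {
      stop("spec includes a year factor but data has no `year` column",
           call. = FALSE)
    }
    if (is.null(year_levels)) year_levels <- sort(unique(data$year))
    for (yr in year_levels[-1]) {
      nm <- paste0("year", yr)
      cols[[nm]] <- as.numeric(data$year == yr)
      k <- k + 1L
      term_cols[[nm]] <- k
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, scaling = scaling, year_levels = year_levels,
       term_cols = term_cols)
}
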