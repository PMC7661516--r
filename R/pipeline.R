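# Single entry point dispatching the analysis tasks, with YAML
# configuration and a JSON run manifest per output directory. The exported
# function is the interface; inst/scripts/reefhurdle-cli.R wraps it for
# shell use.

PIPELINE_TASKS <- c("simulate", "permtest", "fit-sdm", "select",
                    "crossval", "predict", "trends")

#' Read a pipeline configuration file
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file not found: %s", path),
                 class = "reefhurdle_config_error")
  }
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      rlang::abort(sprintf("malformed YAML in %s: %s", path,
                           conditionMessage(e)),
                   class = "reefhurdle_config_error")
    }
  )
  if (!is.list(cfg)) {
    rlang::abort("config must be a YAML mapping.",
                 class = "reefhurdle_config_error")
  }
  cfg
}

write_manifest <- function(out_dir, task, config, seed, inputs, artifacts) {
  digest <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (length(paths) == 0) return(list())
    md5 <- tools::md5sum(paths)
    stats::setNames(as.list(unname(md5)), basename(paths))
  }
  manifest <- list(
    task = task,
    package_version = as.character(utils::packageVersion("reefhurdle")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_digests = digest(inputs),
    artifacts = basename(artifacts),
    artifact_digests = digest(artifacts)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run one pipeline task
#'
#' Dispatches to the module functions: `"simulate"` writes a synthetic
#' dataset bundle; `"permtest"` the permutation ANOVA and pairwise-letter
#' tables; `"fit-sdm"` the hurdle posterior summary; `"select"` the
#' variable-selection score table; `"crossval"` the cross-validation
#' report; `"predict"` a prediction grid with hotspot flags; `"trends"`
#' per-location trend fits, the model comparison and the exclusion report.
#' Every run writes a `manifest.json` with the configuration snapshot,
#' seed and input/artifact digests. Inputs are never mutated; all
#' randomness flows from `seed`.
#'
#' @param task One of `"simulate"`, `"permtest"`, `"fit-sdm"`, `"select"`,
#'   `"crossval"`, `"predict"`, `"trends"`.
#' @param config Named list of options, or a path to a YAML file. Common
#'   keys: `surveys`, `sites` (input CSV paths), `life_stage`, `iterations`,
#'   `draws`, `terms`, `quantile`, `scenario`, `min_total`, `drop_years`.
#' @param overrides Named list merged over `config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list of written artifact paths.
#' @export
run_task <- function(task, config = list(), overrides = list(),
                     out_dir = ".", seed = 1) {
  if (!task %in% PIPELINE_TASKS) {
    rlang::abort(sprintf("unknown task '%s' (expected one of %s)", task,
                         paste(PIPELINE_TASKS, collapse = ", ")),
                 class = "reefhurdle_task_error")
  }
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(config, overrides)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  get_opt <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  inputs <- character()
  artifacts <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }
  load_surveys <- function() {
    path <- get_opt("surveys", NULL)
    if (is.null(path)) {
      rlang::abort("config key 'surveys' (CSV path) is required.",
                   class = "reefhurdle_input_error")
    }
    if (!file.exists(path)) {
      rlang::abort(sprintf("input not found: %s", path),
                   class = "reefhurdle_input_error")
    }
    inputs <<- c(inputs, path)
    read_surveys(path)
  }
  load_sites <- function() {
    path <- get_opt("sites", NULL)
    if (is.null(path) || !file.exists(path)) {
      rlang::abort("config key 'sites' must point to an existing CSV.",
                   class = "reefhurdle_input_error")
    }
    inputs <<- c(inputs, path)
    read_sites(path)
  }
  stage <- get_opt("life_stage", "juvenile")
  spec_from_config <- function() {
    hurdle_spec(
      terms = get_opt("terms", c(BENTHIC_COVARIATES,
                                 ENVIRONMENTAL_COVARIATES)),
      interactions = get_opt("interactions", character()),
      observer_effect = get_opt("observer_effect", TRUE),
      year_factor = get_opt("year_factor", TRUE),
      spatial_field = get_opt("spatial_field", TRUE)
    )
  }
  n_iter <- get_opt("draws", 1500)
  burn <- get_opt("burn", max(200, floor(n_iter / 3)))

  if (task == "simulate") {
    scen <- get_opt("scenario", "abrolhos")
    if (scen == "abrolhos") {
      bundle <- scenario_abrolhos_like(
        seed = seed,
        censuses_per_site_year = get_opt("censuses_per_site_year", 25)
      )
    } else {
      cfg_args <- config[names(config) %in% names(formals(sim_config))]
      cfg_args$seed <- seed
      cfg <- do.call(sim_config, cfg_args)
      sites <- simulate_covariates(cfg)
      sim <- simulate_surveys(cfg, sites)
      bundle <- list(surveys = sim$surveys, sites = sites,
                     truth = sim$truth, config = cfg)
    }
    emit(bundle$surveys, "surveys.csv")
    emit(bundle$sites, "sites.csv")
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(beta_bin = as.list(bundle$truth$beta_bin),
           beta_gam = as.list(bundle$truth$beta_gam),
           year_effect = bundle$truth$year_effect,
           observer_bin = bundle$truth$observer_bin,
           observer_gam = bundle$truth$observer_gam),
      truth_path, auto_unbox = TRUE, digits = NA
    )
    artifacts <- c(artifacts, truth_path)
  } else if (task == "permtest") {
    surveys <- load_surveys()
    df <- add_census_density(surveys[surveys$life_stage == stage, ,
                                     drop = FALSE])
    iter <- get_opt("iterations", 5000)
    an <- perm_anova(df, .data$density, .data$location,
                     iterations = iter, seed = seed)
    pw <- pairwise_perm_test(df, .data$density, .data$location,
                             iterations = iter, seed = seed,
                             adjust = get_opt("adjust", "holm"))
    emit(tidy(an), "anova.csv")
    emit(pw$pairs, "pairwise.csv")
    emit(pw$letters, "letters.csv")
  } else if (task == "fit-sdm") {
    surveys <- load_surveys(); sites <- load_sites()
    fit <- fit_hurdle(surveys, sites, spec_from_config(),
                      life_stage = stage, seed = seed,
                      n_iter = n_iter, burn = burn)
    emit(tidy(fit), "posterior_summary.csv")
    emit(glance(fit), "fit_scores.csv")
    if (isTRUE(get_opt("write_loglik", FALSE))) {
      emit(tibble::as_tibble(fit$binomial$loglik, .name_repair = "minimal"),
           "loglik_binomial.csv")
      emit(tibble::as_tibble(fit$gamma$loglik, .name_repair = "minimal"),
           "loglik_gamma.csv")
    }
  } else if (task == "select") {
    surveys <- load_surveys(); sites <- load_sites()
    sel <- select_model(surveys, sites, spec_from_config(),
                        seed = seed, life_stage = stage,
                        n_iter = n_iter, burn = burn)
    emit(sel$scores, "selection_scores.csv")
    emit(tidy(sel$fit), "posterior_summary.csv")
  } else if (task == "crossval") {
    surveys <- load_surveys(); sites <- load_sites()
    cv <- cross_validate(surveys, sites, spec_from_config(),
                         folds = get_opt("folds", 10),
                         split_fraction = get_opt("split_fraction", 0.5),
                         seed = seed, life_stage = stage,
                         n_iter = n_iter, burn = burn)
    emit(tidy(cv), "cv_folds.csv")
    emit(glance(cv), "cv_summary.csv")
  } else if (task == "predict") {
    surveys <- load_surveys(); sites <- load_sites()
    fit <- fit_hurdle(surveys, sites, spec_from_config(),
                      life_stage = stage, seed = seed,
                      n_iter = n_iter, burn = burn)
    grid <- predict_grid(fit, sites,
                         mode = get_opt("mode", "period-mean"))
    grid <- hotspot_cells(grid, q = get_opt("quantile", 0.9))
    emit(grid, "prediction_grid.csv")
  } else if (task == "trends") {
    surveys <- load_surveys()
    series <- aggregate_counts(surveys,
                               group = get_opt("group", "location"),
                               life_stage = stage)
    guarded <- series_guard(series,
                            min_total = get_opt("min_total", 10),
                            drop_years = unlist(get_opt("drop_years",
                                                        integer())))
    emit(guarded$exclusions, "exclusions.csv")
    locs <- unique(guarded$series$location)
    comp_tbl <- NULL
    fit_tbl <- NULL
    for (lc in locs) {
      ser <- guarded$series[guarded$series$location == lc, , drop = FALSE]
      if (nrow(ser) < 3) next
      cmp <- compare_trends(ser, seed = seed,
                            n_iter = get_opt("draws", 3000),
                            burn = get_opt("burn", 1000))
      comp_tbl <- dplyr::bind_rows(comp_tbl, cmp$table)
      best <- cmp$fits[[cmp$chosen]]
      fit_tbl <- dplyr::bind_rows(
        fit_tbl,
        dplyr::mutate(tidy(best), location = lc, model = cmp$chosen,
                      .before = 1)
      )
    }
    emit(comp_tbl, "model_comparison.csv")
    emit(fit_tbl, "trend_fits.csv")
  }

  write_manifest(out_dir, task, config, seed, inputs, artifacts)
  invisible(c(artifacts, file.path(out_dir, "manifest.json")))
}
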