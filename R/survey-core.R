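# Core data model for stationary visual-census surveys: census geometry,
# density arithmetic, life-stage classification, per-location aggregation,
# and CSV input/output.

SURVEY_COLUMNS <- c(
  "site_id", "location", "mpa_regime", "year", "observer_id",
  "life_stage", "radius_m", "count"
)

SITE_COLUMNS <- c(
  "site_id", "x_km", "y_km",
  "turf", "cca", "fire_coral", "macroalgae", "sponge", "stony_coral",
  "zoanthid", "sst_c", "sss_psu", "depth_m", "rugosity", "dist_land_m"
)

BENTHIC_COVARIATES <- c(
  "turf", "cca", "fire_coral", "macroalgae", "sponge", "stony_coral",
  "zoanthid"
)

ENVIRONMENTAL_COVARIATES <- c(
  "sst_c", "sss_psu", "depth_m", "rugosity", "dist_land_m"
)

#' Sampling area of a stationary visual census
#'
#' A stationary census records every individual within a fixed radius of a
#' point, so the sampled area is the disc area \eqn{\pi r^2}. The survey
#' protocol uses a 2 m radius for juveniles (12.6 m\eqn{^2}) and a 4 m
#' radius for adults (50.2 m\eqn{^2}).
#'
#' @param radius_m Census radius in metres; must be positive.
#' @return Area in square metres.
#' @examples
#' census_area(2)
#' census_area(4)
#' @seealso [census_area_printed()] for the conventional 1-decimal display.
#' @export
census_area <- function(radius_m) {
  if (!is.numeric(radius_m) || any(!is.finite(radius_m)) || any(radius_m <= 0)) {
    stop("`radius_m` must be a positive, finite number.", call. = FALSE)
  }
  pi * radius_m^2
}

#' @rdname census_area
#' @param pi_digits Decimals of \eqn{\pi} used before display rounding;
#'   survey reports conventionally compute disc areas with \eqn{\pi = 3.14},
#'   giving the printed 12.6 and 50.2 m\eqn{^2} (exact \eqn{\pi} would print
#'   50.3 for the 4 m radius).
#' @export
census_area_printed <- function(radius_m, pi_digits = 2) {
  if (any(radius_m <= 0)) {
    stop("`radius_m` must be a positive, finite number.", call. = FALSE)
  }
  round(round(pi, pi_digits) * radius_m^2, 1)
}

#' Density of one visual census
#'
#' Density is count divided by the census disc area, \eqn{N / (\pi r^2)},
#' in individuals per square metre.
#'
#' @param count Non-negative integer count of individuals.
#' @param radius_m Census radius in metres; positive.
#' @return Density (individuals per m\eqn{^2}).
#' @examples
#' census_density(5, 4)
#' @export
census_density <- function(count, radius_m) {
  if (!is.numeric(count) || any(!is.finite(count)) || any(count < 0)) {
    stop("`count` must be a non-negative, finite number.", call. = FALSE)
  }
  if (any(abs(count - round(count)) > 1e-8)) {
    stop("`count` must be a whole number of individuals.", call. = FALSE)
  }
  count / census_area(radius_m)
}

#' Classify an individual's life stage from total length
#'
#' Individuals at or below the threshold (10 cm total length by default,
#' roughly four months old for this parrotfish) are juveniles; all longer
#' individuals are adults. The boundary itself is juvenile.
#'
#' @param total_length_cm Total length in centimetres; positive.
#' @param threshold_cm Juvenile/adult boundary, inclusive for juveniles.
#' @return Character vector of `"juvenile"` / `"adult"`.
#' @examples
#' classify_life_stage(c(4, 10, 10.1))
#' @export
classify_life_stage <- function(total_length_cm, threshold_cm = 10) {
  if (!is.numeric(total_length_cm) || any(!is.finite(total_length_cm)) ||
      any(total_length_cm <= 0)) {
    stop("`total_length_cm` must be positive and finite.", call. = FALSE)
  }
  ifelse(total_length_cm <= threshold_cm, "juvenile", "adult")
}

#' Mean density per group of censuses
#'
#' Aggregates census records to mean density per group, computed as total
#' individuals counted divided by the number of censuses (mean count per
#' census). With `per_m2 = TRUE` each census count is first divided by its
#' disc area so the result is a mean of per-square-metre densities.
#'
#' @param surveys Data frame of census records (see [read_surveys()] for the
#'   schema); must contain the grouping columns, `count`, and `radius_m`.
#' @param ... Grouping columns (tidy-select style), e.g. `location,
#'   life_stage`. Defaults to `location` and `life_stage` when omitted.
#' @param per_m2 Express densities per square metre instead of per census.
#' @return A tibble with the grouping columns, `n_censuses`,
#'   `n_individuals`, and `mean_density`.
#' @examples
#' df <- tibble::tibble(
#'   location = c("A", "A", "A"), life_stage = "juvenile",
#'   count = c(1L, 2L, 0L), radius_m = 2
#' )
#' aggregate_mean_density(df)
#' @export
aggregate_mean_density <- function(surveys, ..., per_m2 = FALSE) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    groups <- rlang::quos(.data$location, .data$life_stage)
  }
  stopifnot(all(c("count", "radius_m") %in% names(surveys)))
  value <- if (per_m2) {
    census_density(surveys$count, surveys$radius_m)
  } else {
    surveys$count
  }
  surveys |>
    dplyr::mutate(.value = value) |>
    dplyr::group_by(!!!groups, .drop = FALSE) |>
    dplyr::summarise(
      n_censuses = dplyr::n(),
      n_individuals = sum(.data$count),
      # an empty group is missing, never zero
      mean_density = ifelse(dplyr::n() == 0, NA_real_,
                            mean(.data$.value)),
      .groups = "drop"
    )
}

validate_surveys <- function(surveys, call_file = "surveys") {
  missing_cols <- setdiff(SURVEY_COLUMNS, names(surveys))
  if (length(missing_cols) > 0) {
    stop(
      sprintf(
        "%s is missing mandatory column(s): %s",
        call_file, paste(missing_cols, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  bad <- which(!is.finite(surveys$count) | surveys$count < 0 |
                 abs(surveys$count - round(surveys$count)) > 1e-8)
  if (length(bad) > 0) {
    stop(
      sprintf(
        "non-integer or negative count at row(s) %s of %s",
        paste(utils::head(bad, 5), collapse = ", "), call_file
      ),
      call. = FALSE
    )
  }
  if (any(!is.finite(surveys$radius_m) | surveys$radius_m <= 0)) {
    stop(sprintf("non-positive census radius in %s", call_file), call. = FALSE)
  }
  invisible(surveys)
}

validate_sites <- function(sites, call_file = "sites") {
  missing_cols <- setdiff(SITE_COLUMNS, names(sites))
  if (length(missing_cols) > 0) {
    stop(
      sprintf(
        "%s is missing mandatory column(s): %s",
        call_file, paste(missing_cols, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  covers <- as.matrix(sites[BENTHIC_COVARIATES])
  if (any(covers < 0 | covers > 1)) {
    stop("benthic cover fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(rowSums(covers) > 1 + 1e-8)) {
    stop("benthic cover fractions of a site must sum to at most 1",
         call. = FALSE)
  }
  if (!all(sites$rugosity %in% c(0, 1))) {
    stop("rugosity must be binary (0 = low, 1 = high)", call. = FALSE)
  }
  invisible(sites)
}

#' Read and write survey and site tables
#'
#' Comma-separated files with a mandatory header, `.` decimal separator and
#' UTF-8 encoding. `read_surveys()` expects the census schema
#' (`site_id, location, mpa_regime, year, observer_id, life_stage, radius_m,
#' count`); `read_sites()` expects the per-site covariate schema
#' (coordinates in km, seven benthic cover fractions, SST, SSS, depth,
#' binary rugosity, distance to land in metres). Unknown extra columns are
#' preserved. Counts must parse as whole numbers; a missing mandatory
#' column raises a schema error naming the column.
#'
#' @param path File path.
#' @param surveys,sites Data frames to write.
#' @return `read_*` return validated tibbles; `write_*` return the input
#'   invisibly.
#' @export
read_surveys <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(SURVEY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop(
      sprintf("%s is missing mandatory column(s): %s",
              path, paste(missing_cols, collapse = ", ")),
      call. = FALSE
    )
  }
  count_raw <- df$count
  count_num <- suppressWarnings(as.numeric(count_raw))
  bad <- which(is.na(count_num) | abs(count_num - round(count_num)) > 1e-8)
  if (length(bad) > 0) {
    stop(
      sprintf("count is not a whole number at data row(s) %s of %s",
              paste(utils::head(bad, 5), collapse = ", "), path),
      call. = FALSE
    )
  }
  df$count <- as.integer(round(count_num))
  df$year <- as.integer(df$year)
  validate_surveys(df, call_file = path)
  df
}

#' @rdname read_surveys
#' @export
read_sites <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sites(df, call_file = path)
  df
}

#' @rdname read_surveys
#' @export
write_surveys <- function(surveys, path) {
  validate_surveys(surveys)
  readr::write_csv(surveys, path, progress = FALSE)
  invisible(surveys)
}

#' @rdname read_surveys
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  readr::write_csv(sites, path, progress = FALSE)
  invisible(sites)
}

#' Per-census densities
#'
#' Adds `area_m2` and `density` (count / area) columns to a survey table.
#'
#' @param surveys Survey data frame with `count` and `radius_m`.
#' @return The input with `area_m2` and `density` columns appended.
#' @export
add_census_density <- function(surveys) {
  validate_surveys(surveys)
  surveys |>
    dplyr::mutate(
      area_m2 = census_area(.data$radius_m),
      density = .data$count / .data$area_m2
    )
}
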