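# Matern covariance for the spatially structured random effect.

#' Matérn covariance function
#'
#' Stationary Matérn covariance with smoothness fixed at \eqn{\nu = 1},
#' the standard choice for spatial residual fields in geostatistical
#' species-distribution models. The range parameter follows the common
#' geostatistical convention \eqn{\kappa = \sqrt{8\nu}/\rho}, so that
#' correlation has dropped to about 0.13 at distance \eqn{\rho}.
#'
#' \deqn{C(d) = \sigma^2 \, (\kappa d) \, K_1(\kappa d), \quad C(0) = \sigma^2}
#'
#' @param dist_km Non-negative distances (km).
#' @param sd Marginal standard deviation \eqn{\sigma_w > 0}.
#' @param range_km Practical range \eqn{\rho_w > 0} (km).
#' @param nu Smoothness; fixed default 1.
#' @return Covariance values, same length as `dist_km`.
#' @examples
#' matern_cov(c(0, 5, 10), sd = 1, range_km = 10)
#' @export
matern_cov <- function(dist_km, sd, range_km, nu = 1) {
  if (!is.numeric(sd) || sd <= 0) {
    stop("`sd` must be positive.", call. = FALSE)
  }
  if (!is.numeric(range_km) || range_km <= 0) {
    stop("`range_km` must be positive.", call. = FALSE)
  }
  if (any(dist_km < 0)) stop("distances must be non-negative.", call. = FALSE)
  kappa <- sqrt(8 * nu) / range_km
  u <- kappa * dist_km
  out <- numeric(length(u))
  zero <- u < 1e-12
  out[zero] <- sd^2
  if (any(!zero)) {
    uu <- u[!zero]
    out[!zero] <- sd^2 * (2^(1 - nu) / gamma(nu)) * uu^nu * besselK(uu, nu)
  }
  out
}

# Covariance matrix over a set of planar coordinates (km).
matern_cov_matrix <- function(coords, sd, range_km, nu = 1, nugget = 1e-8) {
  d <- as.matrix(stats::dist(coords))
  m <- matrix(matern_cov(d, sd, range_km, nu), nrow = nrow(d))
  m + diag(nugget * sd^2, nrow(m))
}
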