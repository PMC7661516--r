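# ggplot2 displays for the main result types.

#' @export
autoplot.trend_fit <- function(object, ...) {
  fitted <- object$fitted
  obs <- fitted[fitted$observed, ]
  ggplot2::ggplot(fitted, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$post_mean),
                       colour = "steelblue") +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$count)) +
    ggplot2::labs(
      x = "Year", y = "Abundance",
      title = sprintf("%s latent Poisson trend - %s",
                      object$model, object$location),
      subtitle = "Posterior mean and 95% credibility band; points are observed totals"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prediction_grid <- function(object, ..., fill = "expected_density") {
  p <- ggplot2::ggplot(
    object[!object$missing, ],
    ggplot2::aes(x = .data$x_km, y = .data$y_km,
                 fill = .data[[fill]])
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = fill) +
    ggplot2::theme_minimal()
  if ("year" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~year)
  }
  p
}

#' @export
autoplot.pairwise_perm <- function(object, ...) {
  lt <- object$letters
  ggplot2::ggplot(lt, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -0.4) +
    ggplot2::labs(
      x = NULL, y = "Group mean",
      subtitle = sprintf(
        "Groups sharing a letter do not differ (pairwise permutation test, alpha = %g)",
        object$alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Mean densities per location with significance letters
#'
#' Convenience display pairing [aggregate_mean_density()] with the compact
#' letters of a [pairwise_perm_test()].
#'
#' @param surveys Survey table.
#' @param pairwise A [pairwise_perm_test()] result computed on the same
#'   grouping.
#' @param life_stage Life stage shown.
#' @return A ggplot object.
#' @export
plot_location_density <- function(surveys, pairwise, life_stage = "juvenile") {
  dens <- aggregate_mean_density(
    surveys[surveys$life_stage == life_stage, , drop = FALSE],
    .data$location
  )
  dens$letters <- pairwise$letters$letters[
    match(dens$location, pairwise$letters$group)]
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$location,
                                     y = .data$mean_density)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters), vjust = -0.4) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Mean density (ind. per census, %s)",
                              life_stage)) +
    ggplot2::theme_minimal()
}
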