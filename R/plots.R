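#' Plot the beta-value distribution of a synthetic cohort
#'
#' Overlays the overall beta-value density with the density restricted to the
#' high-missingness-propensity CpGs, whose distribution is shifted into the
#' mid-range.
#'
#' @param object A `methyl_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.methyl_cohort <- function(object, ...) {
  long <- tidy.methyl_matrix(object$data)
  high <- object$propensity$cpg_id[object$propensity$high_propensity]
  df <- dplyr::bind_rows(
    dplyr::mutate(long, population = "all CpGs"),
    dplyr::mutate(dplyr::filter(long, .data$cpg_id %in% high),
                  population = "high-propensity CpGs")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   colour = .data$population)) +
    ggplot2::geom_density(adjust = 0.5) +
    ggplot2::labs(x = expression(beta ~ "value"), y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot imputation error by beta-value range
#'
#' One panel per mechanism, RMSE (or MAE) against the true-beta bin, coloured
#' by method and line-typed by scale — the standard view showing that
#' mid-range beta-values are harder to impute.
#'
#' @param profile A range profile, as returned by [profile_by_range()] (or a
#'   `benchmark_result`, whose profile is used).
#' @param metric `"rmse"` or `"mae"`.
#' @return A ggplot object.
#' @export
plot_range_profile <- function(profile, metric = c("rmse", "mae")) {
  metric <- match.arg(metric)
  if (inherits(profile, "benchmark_result")) profile <- profile$profile
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin, y = .data[[metric]],
                               colour = .data$method,
                               linetype = .data$scale,
                               group = interaction(.data$method,
                                                   .data$scale))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~mechanism) +
    ggplot2::labs(x = expression("true" ~ beta ~ "range"),
                  y = toupper(metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.benchmark_result <- function(object, ...) {
  plot_range_profile(object)
}
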