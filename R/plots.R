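#' Plot the pooled degree distribution with its power-law fit
#'
#' Log-log scatter of degree frequency with the least-squares line from
#' [fit_powerlaw()].
#'
#' @param object A `powerlaw_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.powerlaw_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = log10(.data$degree), y = log10(.data$freq))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 degree", y = "log10 frequency",
      title = sprintf("Degree distribution (slope %.2f, r² %.2f)",
                      object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot score distributions of curated versus novel inferences
#'
#' Density overlay of a chosen statistic split by curated status; the
#' separation of the two distributions is what the median-threshold
#' classifier exploits.
#'
#' @param scores Tibble from [score_inferences()].
#' @param statistic Score column to plot.
#' @return A ggplot object.
#' @export
plot_score_density <- function(scores, statistic = "w_xya") {
  check_statistic(scores, statistic)
  df <- mutate(scores, class = ifelse(.data$curated, "curated", "novel"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[statistic]], fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = statistic, y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot real-versus-shuffled score differences by stratum
#'
#' Bar chart of the mean matched-pair score difference from
#' [compare_real_vs_shuffled()]; bars above zero indicate real inferences
#' outscoring their degree-preserving randomisations.
#'
#' @param comparison A `shuffle_comparison` tibble.
#' @return A ggplot object.
#' @export
plot_shuffle_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "shuffle_comparison"))
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$stratum, y = .data$mean_difference)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL,
                  y = sprintf("mean difference (%s)", attr(comparison, "statistic"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
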