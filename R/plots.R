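#' Density plot of bootstrap correlation distributions
#'
#' Overlays the observed bootstrap r distribution with its shuffled-age
#' null.
#'
#' @param observed,null `correlation_result` objects.
#' @param measure Label for the plot title.
#' @return A ggplot object.
#' @export
plot_bootstrap_density <- function(observed, null = NULL, measure = "measure") {
  d <- data.frame(r = observed$r_values, distribution = "observed")
  if (!is.null(null)) {
    d <- rbind(d, data.frame(r = null$r_values, distribution = "shuffled null"))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = r, fill = distribution)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "Spearman r", y = "density",
                  title = paste("Bootstrap age correlation:", measure)) +
    ggplot2::theme_minimal()
}

#' Scatter of a per-participant measure against age
#'
#' @param summaries Participant summaries with `age_months` and the measure.
#' @param measure Column name to plot (default `"gap_effect_ms"`).
#' @return A ggplot object.
#' @export
plot_age_trend <- function(summaries, measure = "gap_effect_ms") {
  d <- summaries[!is.na(summaries[[measure]]), ]
  d$.value <- d[[measure]]
  ggplot2::ggplot(d, ggplot2::aes(x = age_months, y = .value)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "age (months)", y = measure) +
    ggplot2::theme_minimal()
}
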