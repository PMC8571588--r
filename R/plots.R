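#' Plot a per-population diversity table
#'
#' Dot plot of observed vs expected heterozygosity per population, with
#' corrected He overlaid when present.
#'
#' @param dt Output of [diversity_table()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(dt) {
  long <- dt |>
    tidyr::pivot_longer(dplyr::any_of(c("ho", "he", "he_corrected")),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pop, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_point(size = 3, position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = NULL, y = "heterozygosity", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gp_pcoa <- function(object, axes = c(1, 2), colour_by = NULL, ...) {
  pts <- object$points
  ax <- paste0("axis_", axes)
  lab <- sprintf("PCoA %d (%.1f%%)", axes, 100 * object$explained[axes])
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]]))
  if (!is.null(colour_by)) {
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                           colour = .data[[colour_by]]))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Plot scenario posterior probabilities
#'
#' @param pp Output of [model_posterior()].
#' @return A ggplot object (bars with 95% CI).
#' @export
plot_scenario_posterior <- function(pp) {
  ggplot2::ggplot(pp, ggplot2::aes(x = stats::reorder(.data$scenario, .data$pp),
                                   y = .data$pp)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.25) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Plot a posterior-predictive model check
#'
#' @param check Output of [model_check()].
#' @return A ggplot object: per-statistic predictive tail fractions; points
#'   outside the `[0.05, 0.95]` band flag poorly reproduced statistics.
#' @export
plot_model_check <- function(check) {
  ggplot2::ggplot(check$tail,
                  ggplot2::aes(x = stats::reorder(.data$statistic,
                                                  .data$fraction_below),
                               y = .data$fraction_below,
                               colour = .data$fits)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.05, 0.95), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of predictive values below observed",
                  colour = "fits") +
    ggplot2::theme_minimal()
}
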