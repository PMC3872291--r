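#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted standard curve
#'
#' Markers and the fitted semilog sizing line, on a log10 mass axis.
#'
#' @param object A [fit_standard_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' autoplot(fit_standard_curve(default_ladder()))
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$markers, ggplot2::aes(x = .data$rf,
                                               y = .data$mass_kda)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "relative migration (rf)", y = "mass (kDa, log scale)",
      title = sprintf("standard curve: log10(kDa) = %.3f %+.3f rf  (R2 = %.4f)",
                      object$intercept, object$slope, object$r2)
    ) +
    ggplot2::theme_minimal()
}

.group_fill <- function() {
  stats::setNames(c("red", "orange", "gold", "forestgreen", "blue", "purple"),
                  as.character(1:6))
}

#' Bar chart of per-group occurrence
#'
#' @param occurrence Output of [group_occurrence()].
#' @return A ggplot.
#' @examples
#' fx <- generate_fixture(frequency_preset("fdb"))
#' plot_group_occurrence(group_occurrence(fx$fibers))
#' @export
plot_group_occurrence <- function(occurrence) {
  ggplot2::ggplot(occurrence,
                  ggplot2::aes(x = factor(.data$group), y = .data$percent,
                               fill = factor(.data$group))) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = .group_fill()) +
    ggplot2::labs(x = "molecular-weight group", y = "% of fibers") +
    ggplot2::theme_minimal()
}

#' Bar chart of the group-multiplicity distribution
#'
#' @param distribution Output of [multiplicity_distribution()].
#' @return A ggplot.
#' @examples
#' fx <- generate_fixture(frequency_preset("soleus"))
#' plot_multiplicity(multiplicity_distribution(fx$fibers))
#' @export
plot_multiplicity <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = factor(.data$n_groups), y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "groups expressed per fiber", y = "% of fibers") +
    ggplot2::theme_minimal()
}

#' Bar chart of expression-pattern frequencies
#'
#' @param tally Output of [tally_patterns()].
#' @return A ggplot.
#' @examples
#' fx <- generate_fixture(frequency_preset("soleus"))
#' plot_pattern_tally(tally_patterns(fx$fibers))
#' @export
plot_pattern_tally <- function(tally) {
  ggplot2::ggplot(tally,
                  ggplot2::aes(x = stats::reorder(.data$groups, -.data$count),
                               y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "expression pattern (group set)", y = "% of fibers") +
    ggplot2::theme_minimal()
}
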