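#' Plot an incidence matrix as a tile map
#'
#' Rows and columns are ordered by decreasing degree, the conventional
#' layout for inspecting nestedness by eye.
#'
#' @param object An `incidence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot incidence_matrix
#' @export
autoplot.incidence_matrix <- function(object, ...) {
  deg_a <- species_degree(object, "ants")
  deg_p <- species_degree(object, "plants")
  d <- tidy.incidence_matrix(object, keep_zeros = TRUE) |>
    dplyr::mutate(
      ant = factor(.data$ant,
                   levels = deg_a$species[order(deg_a$degree)]),
      plant = factor(.data$plant,
                     levels = deg_p$species[order(-deg_p$degree)])
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$plant, y = .data$ant,
                                  fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10") +
    ggplot2::labs(x = "plant species", y = "ant species", fill = "count",
                  title = attr(object, "period")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a Monte-Carlo null distribution with its observed statistic
#'
#' @param object A `null_ensemble` from [nestedness_significance()].
#' @param ... Unused.
#' @return A ggplot object: histogram of the null values with a vertical
#'   line at the observed statistic.
#' @method autoplot null_ensemble
#' @export
autoplot.null_ensemble <- function(object, ...) {
  ggplot2::ggplot(tidy.null_ensemble(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic,
      y = "null draws",
      title = sprintf("%s = %.2f, z = %.2f, P = %.3g", object$statistic,
                      object$observed, object$z, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot of herbivory by species, treatment and year
#'
#' @param stem_means Stem-level herbivory data (e.g. from
#'   [stem_mean_herbivory()]).
#' @return A ggplot object faceted by year.
#' @export
plot_herbivory <- function(stem_means) {
  ggplot2::ggplot(stem_means,
                  ggplot2::aes(x = .data$species, y = .data$herbivory_pct,
                               fill = .data$stem)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~year, ncol = 1) +
    ggplot2::labs(x = NULL, y = "herbivory (% leaf area lost)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "bottom")
}
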