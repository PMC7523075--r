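#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of alpha-diversity estimators by compartment
#'
#' @param alpha Tibble from [iterative_alpha()].
#' @param metric One of `"simpson_complement"`, `"simpson_evenness"`,
#'   `"s_obs"`.
#' @return A ggplot.
#' @export
plot_alpha_diversity <- function(alpha, metric = "simpson_complement") {
  stopifnot(metric %in% names(alpha))
  ggplot2::ggplot(alpha, ggplot2::aes(x = .data$compartment,
                                      y = .data[[metric]],
                                      fill = .data$compartment)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Ordination scatter plot
#'
#' @param object An `mb_ordination`.
#' @param metadata Optional design tibble (joined on `sample_id`).
#' @param colour Metadata column to colour by.
#' @param axes Length-2 integer vector of axes to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.mb_ordination <- function(object, metadata = NULL,
                                   colour = "compartment", axes = c(1, 2),
                                   ...) {
  df <- object$coordinates
  if (!is.null(metadata)) df <- dplyr::left_join(df, metadata, by = "sample_id")
  xs <- paste0("axis", axes[1]); ys <- paste0("axis", axes[2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xs]], y = .data[[ys]]))
  if (!is.null(metadata) && colour %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(caption = sprintf("stress-1 = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Bar chart of PVCA variance components
#'
#' @param x An `mb_pvca` (or its `components` tibble).
#' @return A ggplot.
#' @export
plot_variance_components <- function(x) {
  comp <- if (inherits(x, "mb_pvca")) x$components else as_tibble(x)
  comp$term <- factor(comp$term, levels = comp$term[order(comp$percent)])
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$percent, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "community variation explained (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Quintile plot of paired effect sizes
#'
#' Min-max whiskers, interquartile boxes and medians of the per-plant
#' effect sizes for each OTU of a compartment pair.
#'
#' @param es Tibble from [paired_effect_size()].
#' @return A ggplot.
#' @export
plot_effect_sizes <- function(es) {
  es$otu_id <- factor(es$otu_id, levels = rev(es$otu_id))
  ggplot2::ggplot(es, ggplot2::aes(y = .data$otu_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$es_min, xend = .data$es_max,
                                       yend = .data$otu_id),
                          colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$es_q25, xend = .data$es_q75,
                                       yend = .data$otu_id),
                          linewidth = 2.5, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = .data$es_median), size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("paired effect size (%s vs %s)",
                  es$compartment_a[1], es$compartment_b[1]),
      y = NULL
    ) +
    ggplot2::xlim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Boxplot of plasmid:chromosome ratios by compartment
#'
#' @param ratios Tibble from [replicon_ratio()].
#' @return A ggplot.
#' @export
plot_replicon_ratios <- function(ratios) {
  keep <- dplyr::filter(ratios, !.data$excluded)
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$compartment, y = .data$ratio,
                                     fill = .data$compartment)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~plasmid) +
    ggplot2::labs(x = NULL, y = "plasmid:chromosome reads/Mb ratio") +
    ggplot2::theme_minimal()
}
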