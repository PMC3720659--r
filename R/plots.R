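#' Plot cluster enrichment results
#'
#' Bar plot of the inhibitor fraction per cluster among annotated members,
#' with BH-significant (enriched) clusters highlighted.
#'
#' @param object A `herg_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.herg_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$n_annotated > 0, ]
  df$cluster_id <- stats::reorder(df$cluster_id, -df$fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_id, y = .data$fraction,
                                   fill = .data$bh_significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c23b22", `FALSE` = "grey60"),
                               name = "enriched (BH)") +
    ggplot2::labs(x = "cluster (exemplar id)",
                  y = "inhibitor fraction among annotated members") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot within- versus between-cluster similarity distributions
#'
#' Density comparison of pairwise similarities (expression Pearson or
#' chemical Tanimoto) for pairs inside enriched clusters versus pairs
#' spanning the enriched / non-enriched boundary.
#'
#' @param distributions Tibble from [similarity_distributions()].
#' @param label Axis label for the similarity measure.
#' @return A ggplot object.
#' @export
plot_similarity_distributions <- function(distributions,
                                          label = "pairwise similarity") {
  med <- attr(distributions, "medians")
  ggplot2::ggplot(distributions,
                  ggplot2::aes(x = .data$value, fill = .data$pair_type)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = med, linetype = "dashed") +
    ggplot2::labs(x = label, y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot activity against similarity to enriched exemplars
#'
#' Scatter of measured percent hERG inhibition versus each drug's maximum
#' Pearson correlation to an enriched-cluster exemplar profile.
#'
#' @param analysis Result of [activity_similarity_analysis()].
#' @return A ggplot object.
#' @export
plot_activity_similarity <- function(analysis) {
  ggplot2::ggplot(analysis$per_drug,
                  ggplot2::aes(x = .data$max_cor, y = .data$activity,
                               colour = .data$in_enriched)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "max Pearson correlation to an enriched exemplar",
                  y = "hERG inhibition (%)", colour = "in enriched cluster",
                  subtitle = sprintf("r = %.2f, permutation p %s",
                                     analysis$r, analysis$p_display)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
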