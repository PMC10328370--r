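# ggplot2 displays for design and QC results.

#' Plot a primer pool design
#'
#' Arm melting temperatures per codon, colored by side, with fallback
#' positions marked.
#'
#' @param object A `suni_pool` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.suni_pool <- function(object, ...) {
  long <- object %>%
    select("codon_index", "left_tm", "right_tm", "fallback_used") %>%
    tidyr::pivot_longer(c("left_tm", "right_tm"),
                        names_to = "arm", values_to = "tm") %>%
    mutate(arm = sub("_tm$", "", .data$arm))
  ggplot2::ggplot(long, ggplot2::aes(.data$codon_index, .data$tm,
                                     colour = .data$arm)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$fallback_used), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "codon index (0-based)",
                  y = "arm Tm (°C)", colour = "arm",
                  shape = "fallback") +
    ggplot2::theme_minimal()
}

#' Plot per-position mutation frequencies of a QC run
#'
#' Median programmed-mutation frequency per position with dashed lines at
#' the 10th and 90th percentile of all programmed-variant frequencies (the
#' two quantiles whose log10 ratio is LogDiff).
#'
#' @param object A `qc_result` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_result <- function(object, ...) {
  per <- object$metrics$per_position_median_freq
  freq <- object$table$counts$count / object$table$total_retained
  pop <- freq[freq > 0]
  qs <- quantile(pop, c(0.1, 0.9), type = 7, names = FALSE)
  ggplot2::ggplot(per, ggplot2::aes(.data$codon_index, .data$median_freq)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = qs, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "codon index (0-based)",
                  y = "median programmed-variant frequency") +
    ggplot2::theme_minimal()
}

#' Plot efficiency by 5'-terminal strong/weak class
#'
#' Boxplots of per-position mutagenesis efficiency grouped by the
#' strong/weak class of the left arm's three 5'-terminal bases.
#'
#' @param features A `primer_features` tibble from [featurize_pool()].
#' @return A ggplot object.
#' @export
plot_class_efficiency <- function(features) {
  order_ref <- c("SSS", "SSW", "SWS", "SWW", "WSS", "WSW", "WWS", "WWW")
  features <- features %>%
    mutate(terminal_class = factor(.data$terminal_class, levels = order_ref))
  ggplot2::ggplot(features, ggplot2::aes(.data$terminal_class,
                                         .data$efficiency)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = "5' terminal class (S = G/C, W = A/T)",
                  y = "mutagenesis efficiency") +
    ggplot2::theme_minimal()
}

#' Plot a feature scan
#'
#' Spearman rho of each primer feature against mutagenesis efficiency,
#' ordered by absolute correlation.
#'
#' @param object A `feature_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_scan <- function(object, ...) {
  df <- object %>%
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Spearman ρ vs mutagenesis efficiency",
                  y = NULL) +
    ggplot2::theme_minimal()
}
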