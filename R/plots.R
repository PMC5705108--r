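# ggplot2 methods for the main result types.

#' @describeIn permutation_p Scatter-plot of the two contrasts' t-vectors
#'   (one point per region pair) with the reproducibility R and permutation
#'   p in the subtitle — diagonal scatter means reproducible group
#'   differences.
#' @param object An `fc_repro`.
#' @param ... Unused.
#' @export
autoplot.fc_repro <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_a, y = .data$t_b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = paste0("t (", object$dataset_pair[1], ")"),
      y = paste0("t (", object$dataset_pair[2], ")"),
      title = "Edgewise group-contrast t-values",
      subtitle = sprintf("R = %.3f, permutation p = %.3g (N = %d)",
                         object$r_value, object$p_perm,
                         object$n_permutations)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn split_batch Complementary CDF (1 - CDF) of the per-split
#'   permutation p-values and reproducibility values.
#' @param object An `fc_split_batch`.
#' @param ... Unused.
#' @export
autoplot.fc_split_batch <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("r_value", "p_perm"),
                            names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::stat_ecdf(ggplot2::aes(y = 1 - ggplot2::after_stat(y))) +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(y = "1 - CDF", x = NULL,
                  title = sprintf("Random %s: %d splits",
                                  gsub("_", " ", object$mode),
                                  object$n_splits)) +
    ggplot2::theme_minimal()
}

#' @describeIn split_half_batch Histogram of the per-repeat balanced average
#'   accuracies with the chance level 0.5 marked.
#' @param object An `fc_split_half`.
#' @param ... Unused.
#' @export
autoplot.fc_split_half <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$a_acc)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "balanced average accuracy",
                  title = sprintf("%d half-splits, %s, %d features",
                                  object$n_repeats, object$classifier,
                                  object$n_features)) +
    ggplot2::theme_minimal()
}
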