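# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' Tidy a nested-CV evaluation
#'
#' @param x A `dr_eval`.
#' @param ... Unused.
#' @return Per-outer-fold metrics and chosen configuration, one row per fold.
#' @export
tidy.dr_eval <- function(x, ...) {
  x$folds |>
    select("fold", "n_test", "sensitivity", "specificity", "gmean", "auc",
           "binary_min_occurrence", "inner_score")
}

#' One-row summary of a nested-CV evaluation
#'
#' @param x A `dr_eval`.
#' @param ... Unused.
#' @return A one-row tibble: aggregate sensitivity, specificity, Gmean, AUC,
#'   fold and gene counts.
#' @export
glance.dr_eval <- function(x, ...) {
  bind_cols(x$metrics,
            tibble(n_folds = nrow(x$folds), n_genes = nrow(x$probabilities),
                   algorithm = x$spec$algorithm))
}

#' @export
tidy.dr_importance <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Per-class DR-probability density plot
#'
#' Mirrors the probability-distribution figures used to pick candidate
#' thresholds: one density per class with the classification threshold drawn
#' as a dashed line.
#'
#' @param object A `dr_eval`.
#' @param threshold Classification threshold line (default from the config).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dr_eval <- function(object,
                             threshold = object$config$classification_threshold,
                             ...) {
  ggplot2::ggplot(object$probabilities,
                  ggplot2::aes(x = .data$prob, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Predicted DR probability", y = "Density",
                  fill = "Annotation") +
    ggplot2::theme_minimal()
}

#' Joint-ranking scatter plot
#'
#' Plots the two models' normalized scores for their common genes with the
#' fused top candidates highlighted.
#'
#' @param result_a,result_b `dr_eval` objects.
#' @param mean_cutoff Highlight genes whose mean normalized score exceeds
#'   this (default 0.8).
#' @return A ggplot.
#' @export
plot_joint_scores <- function(result_a, result_b, mean_cutoff = 0.8) {
  pa <- result_a$probabilities
  pb <- result_b$probabilities
  pa$score_a <- normalize_scores(pa$prob)
  pb$score_b <- normalize_scores(pb$prob)
  common <- inner_join_probs(pa, pb) |>
    mutate(mean_score = (.data$score_a + .data$score_b) / 2,
           candidate = .data$label == DR_NEG & .data$mean_score > mean_cutoff)
  ggplot2::ggplot(common, ggplot2::aes(x = .data$score_a, y = .data$score_b,
                                       colour = .data$candidate,
                                       shape = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Model A normalized score", y = "Model B normalized score",
                  colour = "Joint candidate", shape = "Annotation") +
    ggplot2::theme_minimal()
}
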