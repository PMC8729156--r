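# Feature relevance for fitted models, rescaled to [0, 100]. Importance is
# computed on a model fitted to 100% of the genes: the goal is relevance, not
# generalisation (already measured by the nested CV).

new_importance <- function(feature, raw, method) {
  raw <- pmax(raw, 0)
  structure(
    tibble(feature = feature, raw = as.numeric(raw),
           scaled = rescale_0_100(as.numeric(raw)), method = method) |>
      arrange(desc(.data$scaled), .data$feature),
    class = c("dr_importance", "tbl_df", "tbl", "data.frame")
  )
}

#' Impurity (Gini) feature importance of a tree-ensemble model
#'
#' Averages each member tree's summed Gini impurity decrease per splitting
#' feature (features never used in a split score 0), then min-max rescales to
#' \[0, 100\]: 100 is the most important feature, 0 no measured relevance.
#' Only the built-in balanced bagged-tree engine exposes per-feature impurity
#' decreases.
#'
#' @param model A `dr_model` fitted with the balanced bagged-tree engine.
#' @return A `dr_importance` tibble: `feature`, `raw`, `scaled`, `method`.
#' @export
impurity_importance <- function(model) {
  stopifnot(inherits(model, "dr_model"))
  if (!model$spec$algorithm %in% c("balanced-bagged-trees", "balanced-random-forest")) {
    abort("Impurity importance needs the balanced bagged-tree engine.")
  }
  feats <- names(model$feature_map)
  acc <- setNames(numeric(length(feats)), feats)
  for (tree in model$fit$trees) {
    vi <- tree$variable.importance
    if (!is.null(vi)) acc[names(vi)] <- acc[names(vi)] + vi
  }
  acc <- acc / length(model$fit$trees)
  new_importance(unname(model$feature_map), acc, "impurity")
}

#' Permutation feature importance
#'
#' For each feature, permutes its column `n_repeats` times and records the
#' mean drop in training-set Gmean (at the given classification threshold)
#' relative to the unpermuted matrix. Negative drops (noise features that
#' "help" when shuffled) are floored at 0 before the min-max rescale to
#' \[0, 100\]. Gmean is used as the accuracy measure to align with the
#' pipeline's selection metric.
#'
#' @param model A `dr_model`.
#' @param x Feature tibble the model was fitted on (all genes).
#' @param labels Labels tibble.
#' @param n_repeats Permutations per feature (>= 1; default 10).
#' @param seed Integer seed.
#' @param threshold Classification threshold for Gmean (default 0.5).
#' @return A `dr_importance` tibble.
#' @export
permutation_importance <- function(model, x, labels, n_repeats = 10, seed = 42,
                                   threshold = 0.5) {
  stopifnot(inherits(model, "dr_model"))
  if (n_repeats < 1) abort("`n_repeats` must be >= 1.")
  check_labels(labels, require_both_classes = TRUE)
  y <- labels$label[match(x$gene_id, labels$gene_id)]
  base <- metric_set(y, predict(model, x), threshold)$gmean
  feats <- unname(model$feature_map)
  raw <- vapply(seq_along(feats), function(j) {
    fj <- feats[j]
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      withr::with_seed(substream(seed, 500L * j + r), {
        xp[[fj]] <- sample(xp[[fj]])
      })
      base - metric_set(y, predict(model, xp), threshold)$gmean
    }, double(1))
    mean(drops)
  }, double(1))
  new_importance(feats, raw, "permutation")
}

#' @export
autoplot.dr_importance <- function(object, top_n = 20, ...) {
  df <- head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$scaled,
    y = stats::reorder(.data$feature, .data$scaled)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Importance (0-100)", y = NULL,
                  title = sprintf("Top features (%s importance)",
                                  object$method[1])) +
    ggplot2::theme_minimal()
}
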