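# Nested cross-validation engine. The outer loop estimates generalisation;
# the inner loop selects hyperparameters (including the binary
# minimum-occurrence threshold) by mean Gmean. Preprocessing plans and
# undersampling only ever see training instances; every fold records which
# ids its plan and undersample saw, so leakage is checkable after the fact.

#' Geometric mean of sensitivity and specificity
#'
#' The imbalance-robust selection metric: `sqrt(sensitivity * specificity)`.
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @return The geometric mean, in \[0, 1\].
#' @examples
#' gmean(0.87, 0.67)
#' @export
gmean <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) || any(specificity < 0 | specificity > 1)) {
    abort("Sensitivity and specificity must lie in [0, 1].")
  }
  sqrt(sensitivity * specificity)
}

# Rank-statistic (Mann-Whitney) AUC with ties averaged.
rank_auc <- function(y, prob) {
  pos <- y == DR_POS
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

metric_set <- function(y, prob, threshold = 0.5) {
  pred_pos <- prob >= threshold
  pos <- y == DR_POS
  sens <- if (any(pos)) mean(pred_pos[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!pred_pos[!pos]) else NA_real_
  tibble(
    sensitivity = sens, specificity = spec,
    gmean = if (is.na(sens) || is.na(spec)) NA_real_ else gmean(sens, spec),
    auc = rank_auc(y, prob)
  )
}

#' Stratified (optionally grouped) cross-validation folds
#'
#' Assigns instances to `k` folds so that each fold receives a near-equal
#' share of each class. With `groups`, fold assignment happens at the group
#' level (all instances of a group land in one fold) and stratification uses
#' each group's modal label — the scheme needed when several proteins map to
#' one gene and folds must split genes, not proteins.
#'
#' @param labels Labels tibble.
#' @param k Number of folds (must not exceed the minority count, so every
#'   fold can see the minority class).
#' @param seed Integer seed.
#' @param groups Optional: data frame with columns `gene_id`, `group`.
#' @return A tibble `gene_id`, `fold` (integer in `1:k`); folds partition the
#'   instance set.
#' @export
stratified_folds <- function(labels, k, seed = 42, groups = NULL) {
  check_labels(labels, require_both_classes = TRUE)
  k <- as.integer(k)
  if (is.null(groups)) {
    units <- labels |> mutate(unit = .data$gene_id, unit_label = .data$label)
  } else {
    stopifnot(all(c("gene_id", "group") %in% names(groups)))
    units <- labels |>
      left_join(as_tibble(groups), by = "gene_id") |>
      group_by(.data$group) |>
      mutate(unit = .data$group,
             unit_label = names(sort(table(.data$label), decreasing = TRUE))[1]) |>
      ungroup()
  }
  unit_tab <- units |> dplyr::distinct(.data$unit, .data$unit_label)
  n_min <- sum(unit_tab$unit_label == DR_POS)
  if (k > n_min) {
    abort(sprintf("k = %d exceeds the minority count (%d).", k, n_min))
  }
  assign_class <- function(u, offset) {
    u <- sort(u)  # seed maps onto sorted ids: row order never matters
    withr::with_seed(substream(seed, offset), u <- sample(u))
    setNames(rep_len(seq_len(k), length(u)), u)
  }
  fold_of <- c(
    assign_class(unit_tab$unit[unit_tab$unit_label == DR_POS], 11L),
    assign_class(unit_tab$unit[unit_tab$unit_label == DR_NEG], 12L)
  )
  tibble(gene_id = units$gene_id, fold = as.integer(fold_of[units$unit]))
}

#' Undersample a training set to a balanced class ratio
#'
#' Keeps every minority instance and subsamples the majority class without
#' replacement down to the minority count.
#'
#' @param train_ids Gene ids of the training set.
#' @param labels Labels tibble.
#' @param seed Integer seed.
#' @return Sorted character vector of the balanced training ids.
#' @export
undersample <- function(train_ids, labels, seed = 42) {
  check_labels(labels)
  lab <- labels |> filter(.data$gene_id %in% train_ids)
  pos <- lab$gene_id[lab$label == DR_POS]
  neg <- lab$gene_id[lab$label == DR_NEG]
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("Both classes must be present in the training set.")
  }
  withr::with_seed(seed, {
    neg_keep <- if (length(neg) > length(pos)) sample(neg, length(pos)) else neg
  })
  sort(c(pos, neg_keep))
}

expand_grid_configs <- function(spec, thresholds_set) {
  g <- c(spec$grid, list(.threshold_t = as.integer(thresholds_set)))
  df <- expand.grid(g, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Inner-loop hyperparameter and threshold selection
#'
#' Crosses the classifier's hyperparameter grid with the candidate
#' minimum-occurrence thresholds, scores every configuration by mean Gmean
#' over an inner stratified cross-validation (preprocessing fitted on each
#' inner-training part; undersampling applied to the inner-training part only
#' for engines without internal balancing), and returns the argmax — ties
#' broken by grid order.
#'
#' @param x Feature tibble (the outer-training slice).
#' @param labels Labels tibble.
#' @param spec A [dr_classifier()].
#' @param config A [dr_config()]; supplies `inner_folds`, `thresholds_set`,
#'   `univariate_k`, `correlation_cutoff`, `classification_threshold`.
#' @param seed Integer seed.
#' @return List: `params` (best hyperparameters), `binary_min_occurrence`,
#'   `score` (mean inner Gmean), and `table` (all configurations scored).
#' @export
inner_select <- function(x, labels, spec, config = dr_config(), seed = 42) {
  configs <- expand_grid_configs(spec, config$thresholds_set)
  lab <- labels |> filter(.data$gene_id %in% x$gene_id)
  folds <- stratified_folds(lab, min(config$inner_folds, sum(lab$label == DR_POS)),
                            seed = substream(seed, 21L))
  scores <- vapply(seq_along(configs), function(ci) {
    cfg <- configs[[ci]]
    fold_g <- vapply(sort(unique(folds$fold)), function(f) {
      tr_ids <- folds$gene_id[folds$fold != f]
      va_ids <- folds$gene_id[folds$fold == f]
      tryCatch({
        plan <- plan_for_dataset(x[match(tr_ids, x$gene_id), , drop = FALSE],
                                 lab, t = cfg$.threshold_t,
                                 k = config$univariate_k,
                                 cutoff = config$correlation_cutoff)
        if (length(retained_features(plan)) == 0L) return(NA_real_)
        fit_ids <- tr_ids
        if (!spec$handles_imbalance) {
          fit_ids <- undersample(tr_ids, lab, seed = substream(seed, 31L + f))
        }
        xtr <- apply_plan(plan, x[match(fit_ids, x$gene_id), , drop = FALSE])
        model <- fit_model(spec, xtr, lab, params = cfg[names(cfg) != ".threshold_t"],
                           seed = substream(seed, 41L + f))
        xva <- apply_plan(plan, x[match(va_ids, x$gene_id), , drop = FALSE])
        prob <- predict(model, xva)
        y <- lab$label[match(va_ids, lab$gene_id)]
        metric_set(y, prob, config$classification_threshold)$gmean
      }, error = function(e) NA_real_)
    }, double(1))
    if (all(is.na(fold_g))) -Inf else mean(fold_g, na.rm = TRUE)
  }, double(1))
  if (all(!is.finite(scores))) {
    abort("All candidate configurations failed to fit.", class = "drinfer_eval_error")
  }
  best <- which.max(scores)  # first maximum: ties broken by grid order
  cfg <- configs[[best]]
  list(
    params = cfg[names(cfg) != ".threshold_t"],
    binary_min_occurrence = cfg$.threshold_t,
    score = scores[best],
    table = tibble(
      config = purrr::map_chr(configs, function(cc) {
        paste(names(cc), unlist(cc), sep = "=", collapse = ",")
      }),
      mean_gmean = scores
    )
  )
}

#' Nested cross-validation of a classifier on a feature dataset
#'
#' For each outer fold: select hyperparameters and the binary
#' minimum-occurrence threshold on the outer-training set via [inner_select()],
#' fit the preprocessing plan on the outer-training set, refit the best
#' configuration on the (undersampled, for engines without internal
#' balancing) outer-training set, and predict DR probabilities on the
#' untouched test fold. Sensitivity/specificity use the configured
#' classification threshold; AUC is the rank statistic over the fold's
#' probabilities; aggregate metrics are means over folds. Because the outer
#' test folds partition the genes, the concatenated fold predictions form a
#' gene-indexed DR-probability vector alongside the true-label annotation
#' vector — the substrate of candidate inference.
#'
#' @param x Feature tibble.
#' @param labels Labels tibble covering `x`'s genes.
#' @param spec A [dr_classifier()].
#' @param config A [dr_config()].
#' @param groups Optional grouping data frame (`gene_id`, `group`) for
#'   group-aware folds.
#' @param paper_compat Fit the continuous-branch filters (univariate F +
#'   correlation) once on the whole dataset before cross-validation instead
#'   of inside each training fold. This reproduces the original study
#'   design's dataset-level filtering for comparison; it leaks test-fold
#'   information into feature selection and is off by default. The binary
#'   minimum-occurrence filter remains fold-fitted either way, since its
#'   threshold is tuned in the inner loop.
#' @return A `dr_eval` object: `folds` (per-fold metrics, chosen
#'   configuration and instrumentation ids), `probabilities` (tibble
#'   `gene_id`, `label`, `prob`, `fold` covering every instance exactly
#'   once), `metrics` (aggregate means), plus the spec and config.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_genes = 150, n_binary_features = 20,
#'                   n_enriched_features = 4, enrichment_odds = 8, seed = 1)
#' labs <- simulate_labels(cfg)
#' bm <- simulate_binary_matrix(labs, cfg)
#' res <- nested_cv(bm$matrix, labs,
#'                  dr_classifier("balanced-random-forest",
#'                                grid = list(n_trees = 30L)),
#'                  dr_config(outer_folds = 5, thresholds_set = 3, seed = 1))
#' glance(res)
#' }
#' @export
nested_cv <- function(x, labels, spec, config = dr_config(), groups = NULL,
                      paper_compat = FALSE) {
  stopifnot(inherits(spec, "dr_classifier"), inherits(config, "dr_config"))
  lab <- check_labels(labels, require_both_classes = TRUE)
  lab <- lab |> filter(.data$gene_id %in% x$gene_id)
  x <- x[match(lab$gene_id, x$gene_id), , drop = FALSE]
  if (paper_compat) {
    kinds <- feature_kinds(x)
    con <- names(kinds)[kinds == "continuous"]
    if (length(con)) {
      pu <- fit_univariate_k(x[, c("gene_id", con)], lab, config$univariate_k)
      pc <- fit_correlation_filter(x[, c("gene_id", retained_features(pu))],
                                   config$correlation_cutoff)
      x <- x[, c("gene_id", names(kinds)[kinds == "binary"],
                 retained_features(pc))]
    }
  }
  folds <- stratified_folds(lab, config$outer_folds, seed = config$seed,
                            groups = groups)

  fold_rows <- list(); prob_rows <- list()
  for (f in sort(unique(folds$fold))) {
    test_ids <- folds$gene_id[folds$fold == f]
    train_ids <- folds$gene_id[folds$fold != f]
    xtr_full <- x[match(train_ids, x$gene_id), , drop = FALSE]
    sel <- inner_select(xtr_full, lab, spec, config,
                        seed = substream(config$seed, 100L + f))
    plan <- plan_for_dataset(xtr_full, lab, t = sel$binary_min_occurrence,
                             k = config$univariate_k,
                             cutoff = config$correlation_cutoff)
    if (length(retained_features(plan)) == 0L) {
      abort(sprintf("Outer fold %d: preprocessing retained no features.", f),
            class = "drinfer_eval_error")
    }
    fit_ids <- train_ids
    if (!spec$handles_imbalance) {
      fit_ids <- undersample(train_ids, lab,
                             seed = substream(config$seed, 200L + f))
    }
    model <- fit_model(spec, apply_plan(plan, x[match(fit_ids, x$gene_id), ,
                                                drop = FALSE]),
                       lab, params = sel$params,
                       seed = substream(config$seed, 300L + f))
    prob <- predict(model, apply_plan(plan, x[match(test_ids, x$gene_id), ,
                                              drop = FALSE]))
    y <- lab$label[match(test_ids, lab$gene_id)]
    ms <- metric_set(y, prob, config$classification_threshold)
    fold_rows[[f]] <- bind_cols(
      tibble(fold = f, n_test = length(test_ids)), ms,
      tibble(binary_min_occurrence = sel$binary_min_occurrence,
             params = list(sel$params), inner_score = sel$score,
             train_ids = list(train_ids), test_ids = list(test_ids),
             undersample_ids = list(fit_ids),
             plan_fitted_on = list(plan$fitted_on))
    )
    prob_rows[[f]] <- tibble(gene_id = test_ids, label = y,
                             prob = unname(prob), fold = f)
  }
  folds_tb <- bind_rows(fold_rows)
  probs_tb <- bind_rows(prob_rows)
  structure(
    list(
      folds = folds_tb,
      probabilities = probs_tb,
      metrics = tibble(
        sensitivity = mean(folds_tb$sensitivity, na.rm = TRUE),
        specificity = mean(folds_tb$specificity, na.rm = TRUE),
        gmean = mean(folds_tb$gmean, na.rm = TRUE),
        auc = mean(folds_tb$auc, na.rm = TRUE)
      ),
      spec = spec, config = config
    ),
    class = "dr_eval"
  )
}

#' @export
print.dr_eval <- function(x, ...) {
  cat(sprintf("<dr_eval> %s, %d outer folds, %d genes\n",
              x$spec$algorithm, nrow(x$folds), nrow(x$probabilities)))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  Gmean %.3f  AUC %.3f\n",
              x$metrics$sensitivity, x$metrics$specificity,
              x$metrics$gmean, x$metrics$auc))
  invisible(x)
}
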