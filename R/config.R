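#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module. The defaults emulate the
#' statistical structure of the curated ageing-gene sources the pipeline was
#' designed for: a roughly 1:10 minority/majority class ratio, sparse binary
#' annotation matrices with a planted subset of minority-enriched features,
#' DAG-structured annotations obeying the true-path rule, directed pathway
#' graphs, hub-dominated undirected PPI graphs and continuous matrices with
#' controllable class signal.
#'
#' @param n_genes Number of synthetic genes.
#' @param minority_fraction Fraction of genes labelled `"DR"` (minority).
#'   Default 0.10, the roughly tenfold imbalance of the motivating data.
#' @param n_binary_features Number of binary annotation features.
#' @param n_enriched_features Number of planted minority-enriched binary
#'   features (must not exceed `n_binary_features`).
#' @param enrichment_odds Fold increase of the positive-value probability in
#'   the minority class for planted features.
#' @param base_positive_rate Baseline probability of a positive cell.
#' @param n_continuous_features Number of continuous features.
#' @param continuous_effect_size Standardized mean difference (in SD units)
#'   between classes for planted continuous features.
#' @param n_planted_continuous Number of planted continuous features.
#' @param dag_depth,dag_branching Shape of the layered annotation DAG.
#' @param graph_n_nodes,graph_edge_density Shape of simulated graphs.
#' @param seed Integer seed; one global seed drives all generators through
#'   deterministic per-artifact sub-streams.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 1)
#' labs <- simulate_labels(cfg)
#' table(labs$label)
#' @export
sim_config <- function(n_genes = 1000,
                       minority_fraction = 0.10,
                       n_binary_features = 50,
                       n_enriched_features = 5,
                       enrichment_odds = 5,
                       base_positive_rate = 0.05,
                       n_continuous_features = 20,
                       continuous_effect_size = 1,
                       n_planted_continuous = 3,
                       dag_depth = 3,
                       dag_branching = 3,
                       graph_n_nodes = 60,
                       graph_edge_density = 0.08,
                       seed = 42) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    minority_fraction = minority_fraction,
    n_binary_features = as.integer(n_binary_features),
    n_enriched_features = as.integer(n_enriched_features),
    enrichment_odds = enrichment_odds,
    base_positive_rate = base_positive_rate,
    n_continuous_features = as.integer(n_continuous_features),
    continuous_effect_size = continuous_effect_size,
    n_planted_continuous = as.integer(n_planted_continuous),
    dag_depth = as.integer(dag_depth),
    dag_branching = as.integer(dag_branching),
    graph_n_nodes = as.integer(graph_n_nodes),
    graph_edge_density = graph_edge_density,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) abort("`n_genes` must be positive.", class = "drinfer_config_error")
  if (cfg$minority_fraction <= 0 || cfg$minority_fraction >= 1) {
    abort("`minority_fraction` must lie in (0, 1).", class = "drinfer_config_error")
  }
  n_min <- round(cfg$minority_fraction * cfg$n_genes)
  if (n_min < 2 || (cfg$n_genes - n_min) < 2) {
    abort("Each class needs at least 2 genes under the requested fraction.",
          class = "drinfer_config_error")
  }
  if (cfg$n_enriched_features > cfg$n_binary_features) {
    abort("`n_enriched_features` must not exceed `n_binary_features`.",
          class = "drinfer_config_error")
  }
  if (cfg$enrichment_odds <= 0) abort("`enrichment_odds` must be positive.",
                                      class = "drinfer_config_error")
  if (cfg$base_positive_rate < 0 || cfg$base_positive_rate > 1) {
    abort("`base_positive_rate` must lie in [0, 1].", class = "drinfer_config_error")
  }
  if (cfg$dag_depth < 1L) abort("`dag_depth` must be >= 1.", class = "drinfer_config_error")
  if (cfg$graph_n_nodes < 2L) abort("`graph_n_nodes` must be >= 2.",
                                    class = "drinfer_config_error")
  invisible(cfg)
}

#' Pipeline run configuration
#'
#' Defaults mirror the study design the pipeline implements: a 10-fold outer
#' and 5-fold inner nested cross-validation, candidate minimum-occurrence
#' thresholds \{3, 4, 5\} for binary features, a 0.99 absolute-correlation
#' cutoff and a top-1000 univariate F filter for continuous features, a 0.5
#' classification threshold, a 0.01 significance level, and seed 42.
#'
#' @param outer_folds Outer CV folds (>= 2).
#' @param inner_folds Inner CV folds (>= 2).
#' @param thresholds_set Candidate minimum occurrence counts for binary
#'   features, tuned in the inner loop.
#' @param correlation_cutoff Absolute Pearson correlation above which one of a
#'   pair of continuous features is dropped.
#' @param univariate_k Number of continuous features kept by the F-statistic
#'   filter before the correlation pass.
#' @param classification_threshold Probability threshold converting a
#'   DR-probability into a class label.
#' @param significance_level Alpha for enrichment significance flags.
#' @param seed Integer seed.
#' @return An object of class `dr_config` (a named list).
#' @export
dr_config <- function(outer_folds = 10,
                      inner_folds = 5,
                      thresholds_set = c(3, 4, 5),
                      correlation_cutoff = 0.99,
                      univariate_k = 1000,
                      classification_threshold = 0.5,
                      significance_level = 0.01,
                      seed = 42) {
  cfg <- list(
    outer_folds = as.integer(outer_folds),
    inner_folds = as.integer(inner_folds),
    thresholds_set = as.integer(thresholds_set),
    correlation_cutoff = correlation_cutoff,
    univariate_k = as.integer(univariate_k),
    classification_threshold = classification_threshold,
    significance_level = significance_level,
    seed = as.integer(seed)
  )
  class(cfg) <- "dr_config"
  if (cfg$outer_folds < 2L) abort("`outer_folds` must be >= 2.", class = "drinfer_config_error")
  if (cfg$inner_folds < 2L) abort("`inner_folds` must be >= 2.", class = "drinfer_config_error")
  if (cfg$classification_threshold <= 0 || cfg$classification_threshold >= 1) {
    abort("`classification_threshold` must lie in (0, 1).", class = "drinfer_config_error")
  }
  if (length(cfg$thresholds_set) < 1L || any(cfg$thresholds_set < 1L)) {
    abort("`thresholds_set` must contain integers >= 1.", class = "drinfer_config_error")
  }
  cfg
}
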