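# Training-fold-fitted feature filters. A fitted plan records which features
# survive and why; applying it to any matrix just selects columns, so plans
# fitted on a training fold can be applied to held-out genes without leakage.

new_plan <- function(table, fitted_on) {
  structure(list(table = table, fitted_on = fitted_on), class = "dr_plan")
}

#' @export
print.dr_plan <- function(x, ...) {
  cat(sprintf("<dr_plan> %d/%d features retained (fitted on %d genes)\n",
              sum(x$table$retained), nrow(x$table), length(x$fitted_on)))
  invisible(x)
}

#' Retained feature ids of a fitted plan
#' @param plan A `dr_plan`.
#' @return Character vector of retained feature ids.
#' @export
retained_features <- function(plan) {
  plan$table$feature[plan$table$retained]
}

#' Apply a fitted preprocessing plan
#'
#' @param plan A `dr_plan`.
#' @param x Feature tibble.
#' @return `x` restricted to the plan's retained features (plus `gene_id`).
#' @export
apply_plan <- function(plan, x) {
  keep <- intersect(c("gene_id", retained_features(plan)), names(x))
  missing <- setdiff(retained_features(plan), names(x))
  if (length(missing)) {
    abort(sprintf("Matrix lacks %d features the plan retains.", length(missing)))
  }
  x[, c("gene_id", retained_features(plan)), drop = FALSE]
}

#' Minimum-occurrence filter for binary features
#'
#' Retains the binary features with at least `t` positive cells among the
#' fitting instances — the tunable sparsity filter whose threshold `t` is a
#' member of the run configuration's `thresholds_set` and is selected in the
#' inner cross-validation loop.
#'
#' @param x Binary feature tibble.
#' @param t Minimum number of positive cells (>= 1).
#' @return A `dr_plan`.
#' @export
fit_min_occurrence <- function(x, t) {
  stopifnot(t >= 1)
  m <- fm_matrix(x)
  if (ncol(m)) {
    vals <- m[!is.na(m)]
    if (length(vals) && !all(vals %in% c(0, 1))) {
      abort("`fit_min_occurrence()` needs a binary matrix.", class = "drinfer_type_error")
    }
  }
  pos <- colSums(m == 1, na.rm = TRUE)
  new_plan(
    tibble(feature = colnames(m), branch = "binary",
           statistic = as.numeric(pos), retained = pos >= t),
    fitted_on = x$gene_id
  )
}

#' Greedy high-correlation filter for continuous features
#'
#' Walks the columns in order; a feature is dropped iff its absolute Pearson
#' correlation with an already-retained feature exceeds `cutoff` (so of any
#' correlated pair the earlier column is kept — a deterministic tie-break).
#' Zero-variance columns have their correlations treated as 0 and are
#' retained unless they duplicate an earlier constant column, with a warning.
#'
#' @param x Continuous feature tibble (>= 2 instances).
#' @param cutoff Absolute correlation threshold (default 0.99).
#' @return A `dr_plan`.
#' @export
fit_correlation_filter <- function(x, cutoff = 0.99) {
  m <- fm_matrix(x)
  if (nrow(m) < 2L) abort("Need at least 2 instances to estimate correlations.")
  p <- ncol(m)
  const <- apply(m, 2L, function(v) var(v, na.rm = TRUE) %in% c(0, NA) ||
                   is.na(var(v, na.rm = TRUE)))
  if (any(const)) warn("Zero-variance column(s): correlation treated as 0.")
  cm <- suppressWarnings(abs(cor(m, use = "pairwise.complete.obs")))
  cm[!is.finite(cm)] <- 0
  retained <- logical(p)
  for (j in seq_len(p)) {
    kept <- which(retained)
    drop_j <- FALSE
    if (length(kept)) {
      if (const[j]) {
        # a constant duplicates an earlier retained constant -> drop
        drop_j <- any(const[kept] & vapply(kept, function(k) {
          identical(m[, k], m[, j])
        }, logical(1)))
      } else {
        drop_j <- any(cm[j, kept] > cutoff)
      }
    }
    retained[j] <- !drop_j
  }
  max_cor <- vapply(seq_len(p), function(j) {
    kept <- setdiff(which(retained), j)
    if (length(kept) == 0L) 0 else max(cm[j, kept])
  }, double(1))
  new_plan(
    tibble(feature = colnames(m), branch = "continuous",
           statistic = max_cor, retained = retained),
    fitted_on = x$gene_id
  )
}

# One-way ANOVA F statistic of each column against a binary label.
univariate_f <- function(m, y) {
  y <- factor(y)
  n1 <- sum(y == levels(y)[1]); n2 <- sum(y == levels(y)[2])
  apply(m, 2L, function(v) {
    g1 <- v[y == levels(y)[1]]; g2 <- v[y == levels(y)[2]]
    gm <- mean(v, na.rm = TRUE)
    ssb <- n1 * (mean(g1, na.rm = TRUE) - gm)^2 + n2 * (mean(g2, na.rm = TRUE) - gm)^2
    ssw <- sum((g1 - mean(g1, na.rm = TRUE))^2, na.rm = TRUE) +
      sum((g2 - mean(g2, na.rm = TRUE))^2, na.rm = TRUE)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / 1) / (ssw / (n1 + n2 - 2))
  })
}

#' Top-k univariate F-statistic filter
#'
#' Retains the `k` continuous features with the largest one-way ANOVA F
#' statistic against the binary class label (all features if fewer than `k`).
#' Constant features score F = 0 and rank last.
#'
#' @param x Continuous feature tibble.
#' @param labels Labels tibble covering `x`'s genes (both classes present).
#' @param k Number of features to keep (default 1000).
#' @return A `dr_plan`.
#' @export
fit_univariate_k <- function(x, labels, k = 1000) {
  check_labels(labels)
  m <- fm_matrix(x)
  y <- labels$label[match(rownames(m), labels$gene_id)]
  if (length(unique(y)) < 2L) {
    abort("Both classes must be present to compute F statistics.")
  }
  f <- univariate_f(m, y)
  ord <- order(-f, seq_along(f))  # ties keep earlier columns
  retained <- logical(ncol(m))
  retained[ord[seq_len(min(k, ncol(m)))]] <- TRUE
  new_plan(
    tibble(feature = colnames(m), branch = "continuous",
           statistic = as.numeric(f), retained = retained),
    fitted_on = x$gene_id
  )
}

#' Dispatching preprocessing plan for a mixed matrix
#'
#' Splits features by realized kind — a column routed to the binary branch
#' iff its non-missing values are a subset of \{0, 1\}, which also captures
#' nominally continuous features that realize only two values — then fits the
#' minimum-occurrence filter on the binary branch and the univariate-F filter
#' followed by the correlation filter on the continuous branch. The final
#' plan retains the union of both branches. All statistics are computed from
#' the fitting instances only.
#'
#' @param x Feature tibble.
#' @param labels Labels tibble.
#' @param t Minimum-occurrence threshold for the binary branch.
#' @param k Univariate top-k for the continuous branch.
#' @param cutoff Correlation cutoff for the continuous branch.
#' @return A `dr_plan` whose table records each feature's branch.
#' @export
plan_for_dataset <- function(x, labels, t = 3, k = 1000, cutoff = 0.99) {
  kinds <- feature_kinds(x)
  bin_cols <- names(kinds)[kinds == "binary"]
  con_cols <- names(kinds)[kinds == "continuous"]
  tabs <- list()
  if (length(bin_cols)) {
    pb <- fit_min_occurrence(x[, c("gene_id", bin_cols)], t)
    tabs <- c(tabs, list(pb$table))
  }
  if (length(con_cols)) {
    pu <- fit_univariate_k(x[, c("gene_id", con_cols)], labels, k)
    surv <- retained_features(pu)
    pc <- fit_correlation_filter(x[, c("gene_id", surv)], cutoff)
    tab <- pu$table
    tab$retained <- tab$feature %in% retained_features(pc)
    tabs <- c(tabs, list(tab))
  }
  tab <- bind_rows(tabs)
  # preserve original column order
  tab <- tab[match(names(kinds), tab$feature), ]
  new_plan(tab, fitted_on = x$gene_id)
}

#' @export
tidy.dr_plan <- function(x, ...) x$table
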