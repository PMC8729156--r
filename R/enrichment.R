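# Statistical characterisation of predictive features: class-proportion
# tests for binary features, Welch t-tests for continuous ones, and
# Benjamini-Hochberg adjustment across the feature family.

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' Tests whether the proportion of minority-class genes carrying a feature's
#' positive value differs from the majority-class proportion. With a
#' degenerate pooled proportion (0 or 1, i.e. the feature is constant across
#' both groups) the p-value is 1.
#'
#' @param a Positive count in group 1 (of `n1`).
#' @param n1 Group 1 size (>= 1).
#' @param b Positive count in group 2 (of `n2`).
#' @param n2 Group 2 size (>= 1).
#' @return Two-sided p-value.
#' @examples
#' two_proportion_test(20, 110, 38, 876)
#' @export
two_proportion_test <- function(a, n1, b, n2) {
  stopifnot(n1 >= 1, n2 >= 1, a >= 0, a <= n1, b >= 0, b <= n2)
  p_pool <- (a + b) / (n1 + n2)
  if (p_pool %in% c(0, 1)) return(1)
  z <- (a / n1 - b / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  2 * pnorm(-abs(z))
}

#' Welch two-sample t-test p-value
#'
#' Two-sided unequal-variance t-test comparing a continuous feature between
#' the two classes. Degenerate input (both groups constant and equal, a 0/0
#' statistic) returns p = 1 with a warning.
#'
#' @param x_minority,x_majority Numeric vectors (>= 2 values each).
#' @return Two-sided p-value.
#' @export
welch_t_test <- function(x_minority, x_majority) {
  if (length(x_minority) < 2L || length(x_majority) < 2L) {
    abort("Each group needs at least 2 values.")
  }
  if (sd(x_minority) == 0 && sd(x_majority) == 0) {
    if (mean(x_minority) == mean(x_majority)) {
      warn("Both groups constant and equal; p set to 1.")
      return(1)
    }
    return(0)
  }
  stats::t.test(x_minority, x_majority, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement
#' (delegates to [stats::p.adjust()]); order-preserving on ranks.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Enrichment table for binary features
#'
#' For each requested feature: the minority/majority positive counts and
#' proportions (percent, 2 decimals), the raw two-proportion z-test p-value,
#' the BH-adjusted p-value, and a significance flag at `alpha`. The BH family
#' is, by default, all features of the matrix — adjusting only a shortlist
#' would understate multiplicity — with the shortlisted rows extracted
#' afterwards; set `family = "selected"` to adjust over `features` only.
#'
#' @param x Binary feature tibble.
#' @param labels Labels tibble.
#' @param features Feature ids to report (default: all).
#' @param alpha Significance level (default 0.01).
#' @param family `"all"` (default) or `"selected"`: the multiple-testing
#'   family over which BH runs.
#' @return A tibble, one row per requested feature: `feature`, `minority_pos`,
#'   `n_minority`, `majority_pos`, `n_majority`, `minority_pct`,
#'   `majority_pct`, `p_value`, `adj_p_value`, `significant`.
#' @export
enrichment_table <- function(x, labels, features = NULL, alpha = 0.01,
                             family = c("all", "selected")) {
  family <- match.arg(family)
  check_labels(labels, require_both_classes = TRUE)
  m <- fm_matrix(x)
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    abort("`enrichment_table()` expects binary features.")
  }
  if (is.null(features)) features <- colnames(m)
  missing <- setdiff(features, colnames(m))
  if (length(missing)) {
    abort(sprintf("Unknown features: %s", paste(head(missing, 3), collapse = ", ")))
  }
  y <- labels$label[match(rownames(m), labels$gene_id)]
  fam_feats <- if (family == "all") colnames(m) else features
  n1 <- sum(y == DR_POS); n2 <- sum(y == DR_NEG)
  counts <- tibble(
    feature = fam_feats,
    minority_pos = unname(colSums(m[y == DR_POS, fam_feats, drop = FALSE] == 1,
                                  na.rm = TRUE)),
    majority_pos = unname(colSums(m[y == DR_NEG, fam_feats, drop = FALSE] == 1,
                                  na.rm = TRUE))
  )
  counts$p_value <- purrr::map2_dbl(counts$minority_pos, counts$majority_pos,
                                    function(a, b) two_proportion_test(a, n1, b, n2))
  counts$adj_p_value <- benjamini_hochberg(counts$p_value)
  counts |>
    filter(.data$feature %in% features) |>
    mutate(
      n_minority = n1, n_majority = n2,
      minority_pct = round(100 * .data$minority_pos / n1, 2),
      majority_pct = round(100 * .data$majority_pos / n2, 2),
      significant = .data$adj_p_value < alpha
    ) |>
    select("feature", "minority_pos", "n_minority", "majority_pos",
           "n_majority", "minority_pct", "majority_pct", "p_value",
           "adj_p_value", "significant")
}
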