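# Candidate inference: majority-annotated genes confidently predicted as
# minority ("strong false positives") are novel DR-relatedness hypotheses;
# two models' score vectors are min-max normalized, intersected and averaged
# to form a joint ranking.

eval_probabilities <- function(result) {
  if (inherits(result, "dr_eval")) result$probabilities else as_tibble(result)
}

#' Rank strong false positives as DR candidates
#'
#' Filters the evaluation's probability vector to majority-annotated
#' (`"NotDR"`) genes whose predicted DR probability reaches `threshold`, and
#' ranks them by descending probability (ties broken by gene id). The top
#' `top_k` are flagged as the headline candidates. An empty result (no
#' majority gene over threshold) is valid, not an error.
#'
#' @param result A `dr_eval` or a tibble with `gene_id`, `label`, `prob`.
#' @param threshold Minimum DR probability (default 0.5, the classification
#'   threshold).
#' @param top_k Number of genes to flag (default 10).
#' @return A tibble `gene_id`, `label`, `prob`, `rank`, `top_k`.
#' @export
false_positive_ranking <- function(result, threshold = 0.5, top_k = 10) {
  pr <- eval_probabilities(result)
  pr |>
    filter(.data$label == DR_NEG, .data$prob >= threshold) |>
    arrange(desc(.data$prob), .data$gene_id) |>
    mutate(rank = row_number(), top_k = .data$rank <= top_k) |>
    select("gene_id", "label", "prob", "rank", "top_k")
}

#' Min-max normalize a probability vector to [0, 1]
#'
#' Affine map over the model's full gene set, so the two models' score
#' distributions become comparable before averaging. A constant vector has
#' no spread to map and raises an error.
#'
#' @param prob Numeric vector (>= 2 distinct values).
#' @return Numeric vector in \[0, 1\], order-preserving.
#' @export
normalize_scores <- function(prob) {
  rng <- range(prob)
  if (diff(rng) == 0) abort("Cannot normalize a constant score vector.")
  (prob - rng[1]) / (rng[2] - rng[1])
}

#' Joint candidate ranking across two models
#'
#' Each model's DR-probability vector is min-max normalized over its own full
#' gene set; the gene sets are then intersected, the two normalized scores
#' averaged, and the majority-annotated common genes with mean score above
#' `mean_cutoff` reported — together with each model's rank of the gene among
#' the common majority-class genes.
#'
#' @param result_a,result_b `dr_eval` objects (or probability tibbles).
#' @param mean_cutoff Minimum mean normalized score (default 0.8).
#' @return A tibble `gene_id`, `score_a`, `score_b`, `mean_score`,
#'   `joint_rank`, `rank_a`, `rank_b`.
#' @export
joint_ranking <- function(result_a, result_b, mean_cutoff = 0.8) {
  pa <- eval_probabilities(result_a)
  pb <- eval_probabilities(result_b)
  pa$score_a <- normalize_scores(pa$prob)
  pb$score_b <- normalize_scores(pb$prob)
  common <- inner_join_probs(pa, pb)
  if (nrow(common) == 0L) {
    abort("The two models share no genes.", class = "drinfer_validation_error")
  }
  common <- common |> mutate(mean_score = (.data$score_a + .data$score_b) / 2)
  maj <- common |>
    filter(.data$label == DR_NEG) |>
    mutate(rank_a = rank(-.data$score_a, ties.method = "min"),
           rank_b = rank(-.data$score_b, ties.method = "min")) |>
    filter(.data$mean_score > mean_cutoff) |>
    arrange(desc(.data$mean_score), .data$gene_id) |>
    mutate(joint_rank = row_number()) |>
    select("gene_id", "score_a", "score_b", "mean_score", "joint_rank",
           "rank_a", "rank_b")
  maj
}

inner_join_probs <- function(pa, pb) {
  dplyr::inner_join(
    pa |> select("gene_id", "label", "score_a"),
    pb |> select("gene_id", "score_b"),
    by = "gene_id"
  )
}

#' Pearson correlation of two models' normalized scores
#'
#' Computed over the common genes, overall and within each class stratum.
#'
#' @param result_a,result_b `dr_eval` objects (or probability tibbles).
#' @return A tibble `stratum` (`overall`, `minority`, `majority`), `r`, `n`.
#' @export
score_correlation <- function(result_a, result_b) {
  pa <- eval_probabilities(result_a)
  pb <- eval_probabilities(result_b)
  pa$score_a <- normalize_scores(pa$prob)
  pb$score_b <- normalize_scores(pb$prob)
  common <- inner_join_probs(pa, pb)
  strata <- list(
    overall = common,
    minority = common |> filter(.data$label == DR_POS),
    majority = common |> filter(.data$label == DR_NEG)
  )
  purrr::imap(strata, function(df, nm) {
    if (nrow(df) < 3L) {
      abort(sprintf("Stratum '%s' has fewer than 3 common genes.", nm))
    }
    tibble(stratum = nm, r = cor(df$score_a, df$score_b), n = nrow(df))
  }) |> bind_rows()
}

#' Per-class DR-probability histogram and density peak
#'
#' Bins each class's predicted probabilities over \[0, 1\] (bins partition
#' the interval, so counts sum to the class sizes) and locates each class's
#' density peak — the probability value of maximal kernel density (for a
#' class with a single distinct value, that value).
#'
#' @param result A `dr_eval` or probability tibble.
#' @param bins Number of equal-width bins (default 20).
#' @return A list: `histogram` (tibble `label`, `bin_lower`, `bin_upper`,
#'   `count`) and `peaks` (tibble `label`, `peak`).
#' @export
probability_density_summary <- function(result, bins = 20) {
  pr <- eval_probabilities(result)
  brk <- seq(0, 1, length.out = bins + 1L)
  hist_tb <- pr |>
    group_by(.data$label) |>
    summarise(.bins = list(table(cut(.data$prob, breaks = brk,
                                     include.lowest = TRUE))),
              .groups = "drop") |>
    mutate(counts = purrr::map(.data$.bins, as.integer)) |>
    select(-".bins") |>
    mutate(bin_lower = list(brk[-length(brk)]), bin_upper = list(brk[-1])) |>
    tidyr::unnest(c("counts", "bin_lower", "bin_upper")) |>
    rename(count = "counts") |>
    select("label", "bin_lower", "bin_upper", "count")
  peaks <- pr |>
    group_by(.data$label) |>
    summarise(peak = {
      v <- .data$prob
      if (length(unique(v)) < 2L) unique(v)[1]
      else {
        d <- density(v, from = 0, to = 1)
        d$x[which.max(d$y)]
      }
    }, .groups = "drop")
  list(histogram = hist_tb, peaks = peaks)
}
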