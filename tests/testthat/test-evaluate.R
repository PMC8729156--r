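test_that("gmean is the geometric mean and rejects out-of-range inputs", {
  expect_equal(gmean(1, 1), 1)
  expect_equal(gmean(0, 0.9), 0)
  expect_equal(gmean(0.77, 0.77), 0.77)
  expect_error(gmean(1.2, 0.5), "\\[0, 1\\]")
})

test_that("stratified folds partition instances with per-fold minority coverage", {
  labs <- toy_labels(10, 90)
  folds <- stratified_folds(labs, k = 10, seed = 7)
  # partition: union = all ids, pairwise disjoint
  expect_setequal(folds$gene_id, labs$gene_id)
  expect_false(anyDuplicated(folds$gene_id) > 0)
  per_fold <- table(folds$fold, labs$label[match(folds$gene_id, labs$gene_id)])
  expect_true(all(per_fold[, "DR"] == 1))   # exactly 1 minority per fold
  expect_true(all(per_fold[, "NotDR"] == 9))
  expect_error(stratified_folds(labs, k = 11, seed = 1), "minority")
})

test_that("fold assignment is invariant to instance order", {
  labs <- toy_labels(8, 40)
  shuffled <- withr::with_seed(2, labs[sample(nrow(labs)), ])
  f1 <- stratified_folds(labs, k = 4, seed = 3)
  f2 <- stratified_folds(shuffled, k = 4, seed = 3)
  expect_equal(dplyr::arrange(f1, gene_id), dplyr::arrange(f2, gene_id))
})

test_that("grouped folds never split a group across folds", {
  labs <- toy_labels(6, 18)
  groups <- tibble::tibble(
    gene_id = labs$gene_id,
    group = rep(sprintf("G%d", 1:8), each = 3)
  )
  folds <- stratified_folds(labs, k = 2, seed = 5, groups = groups)
  joined <- dplyr::left_join(folds, groups, by = "gene_id")
  per_group <- tapply(joined$fold, joined$group, function(f) length(unique(f)))
  expect_true(all(per_group == 1))
})

test_that("undersampling balances classes deterministically", {
  labs <- toy_labels(10, 100)
  ids <- undersample(labs$gene_id, labs, seed = 4)
  expect_length(ids, 20)
  got <- table(labs$label[match(ids, labs$gene_id)])
  expect_equal(unname(got["DR"]), 10, ignore_attr = TRUE)
  expect_equal(unname(got["NotDR"]), 10, ignore_attr = TRUE)
  expect_identical(ids, undersample(labs$gene_id, labs, seed = 4))

  bal <- toy_labels(9, 9)
  expect_setequal(undersample(bal$gene_id, bal, seed = 1), bal$gene_id)
  only_pos <- dplyr::filter(labs, label == "DR")
  expect_error(undersample(only_pos$gene_id, labs, seed = 1), "Both classes")
})

test_that("inner selection returns the single config unchallenged and breaks ties by order", {
  cfg <- sim_config(n_genes = 80, n_binary_features = 15, n_enriched_features = 4,
                    enrichment_odds = 10, base_positive_rate = 0.08, seed = 17)
  labs <- simulate_labels(cfg)
  x <- simulate_binary_matrix(labs, cfg)$matrix
  spec1 <- dr_classifier("balanced-random-forest", grid = list(n_trees = 20L))
  run <- dr_config(outer_folds = 3, inner_folds = 3, thresholds_set = 3, seed = 1)
  sel <- inner_select(x, labs, spec1, run, seed = 2)
  expect_equal(sel$params$n_trees, 20L)
  expect_equal(sel$binary_min_occurrence, 3L)
  expect_equal(nrow(sel$table), 1)

  # two identical configurations: the first wins
  spec2 <- dr_classifier("balanced-random-forest", grid = list(n_trees = c(20L, 20L)))
  sel2 <- inner_select(x, labs, spec2, run, seed = 2)
  expect_equal(sel2$table$mean_gmean[1], sel2$table$mean_gmean[2])
  expect_equal(which.max(sel2$table$mean_gmean), 1L)
})

test_that("inner selection picks the occurrence threshold that keeps the signal", {
  # signal features carry exactly 4 minority positives: t = 5 filters them
  # out, t = 3 keeps them, so the inner Gmean must favour t = 3
  labs <- toy_labels(8, 72)
  withr::with_seed(23, {
    m <- matrix(rbinom(80 * 10, 1, 0.02), 80, 10)
    for (j in 1:3) {
      m[, j] <- 0
      m[sample(which(labs$label == "DR"), 4), j] <- 1
    }
    x <- toy_matrix(m, gene_ids = labs$gene_id)
  })
  spec <- dr_classifier("balanced-random-forest", grid = list(n_trees = 40L))
  run <- dr_config(outer_folds = 2, inner_folds = 4, thresholds_set = c(3, 5), seed = 1)
  sel <- inner_select(x, labs, spec, run, seed = 6)
  expect_equal(sel$binary_min_occurrence, 3L)
  # oracle: exhaustive inner table confirms t = 3 strictly beats t = 5
  expect_gt(sel$table$mean_gmean[1], sel$table$mean_gmean[2])
})

test_that("nested CV output is structurally sound", {
  cfg <- sim_config(n_genes = 120, n_binary_features = 20, n_enriched_features = 5,
                    enrichment_odds = 8, base_positive_rate = 0.06, seed = 19)
  labs <- simulate_labels(cfg)
  x <- simulate_binary_matrix(labs, cfg)$matrix
  spec <- dr_classifier("balanced-random-forest", grid = list(n_trees = 25L))
  res <- nested_cv(x, labs, spec,
                   dr_config(outer_folds = 4, inner_folds = 3,
                             thresholds_set = 3, seed = 2))
  # probability vector covers every instance exactly once
  expect_setequal(res$probabilities$gene_id, labs$gene_id)
  expect_equal(nrow(res$probabilities), nrow(labs))
  # annotation vector equals the input labels
  expect_equal(res$probabilities$label,
               labs$label[match(res$probabilities$gene_id, labs$gene_id)])
  # outer test folds partition the instance set
  test_sets <- res$folds$test_ids
  expect_setequal(unlist(test_sets), labs$gene_id)
  expect_equal(sum(lengths(test_sets)), nrow(labs))
  # metrics in range; per-fold gmean consistency
  expect_true(all(res$folds$sensitivity >= 0 & res$folds$sensitivity <= 1))
  expect_true(all(res$folds$specificity >= 0 & res$folds$specificity <= 1))
  expect_equal(res$folds$gmean,
               sqrt(res$folds$sensitivity * res$folds$specificity))
  expect_true(all(res$probabilities$prob >= 0 & res$probabilities$prob <= 1))
  g <- glance(res)
  expect_equal(g$n_folds, 4)
  td <- tidy(res)
  expect_equal(nrow(td), 4)
})

test_that("probabilities carry signal with the xgboost adapter too", {
  cfg <- sim_config(n_genes = 150, n_binary_features = 15, n_enriched_features = 5,
                    enrichment_odds = 10, base_positive_rate = 0.06, seed = 29)
  labs <- simulate_labels(cfg)
  x <- simulate_binary_matrix(labs, cfg)$matrix
  spec <- dr_classifier("gradient-boosting-xgb",
                        grid = list(nrounds = 20L, max_depth = 2L))
  res <- nested_cv(x, labs, spec,
                   dr_config(outer_folds = 3, inner_folds = 3,
                             thresholds_set = 3, seed = 3))
  expect_gt(res$metrics$auc, 0.6)
  # xgb has no internal balancing: its training sets were undersampled
  expect_true(all(lengths(res$folds$undersample_ids) <
                    lengths(res$folds$train_ids)))
})

test_that("unknown and unavailable algorithms are rejected", {
  expect_error(dr_classifier("quantum-forest"), "Unknown algorithm")
  expect_error(dr_classifier("gradient-boosting-cat"), "CatBoost")
  expect_error(dr_classifier("balanced-random-forest", grid = list()), "nonempty")
})

test_that("dataset-level filter compatibility mode pre-restricts continuous features", {
  labs <- toy_labels(8, 32)
  withr::with_seed(61, {
    bin <- matrix(rbinom(40 * 6, 1, 0.3), 40, 6)
    con <- matrix(rnorm(40 * 10), 40, 10)
    con[labs$label == "DR", 1] <- con[labs$label == "DR", 1] + 6
    x <- toy_matrix(cbind(bin, con), gene_ids = labs$gene_id,
                    feature_ids = c(paste0("b", 1:6), paste0("c", 1:10)))
  })
  spec <- dr_classifier("balanced-random-forest", grid = list(n_trees = 15L))
  run <- dr_config(outer_folds = 3, inner_folds = 3, thresholds_set = 3,
                   univariate_k = 2, seed = 4)
  res <- nested_cv(x, labs, spec, run, paper_compat = TRUE)
  # only the 2 globally F-selected continuous features can appear in any plan
  global_keep <- retained_features(
    fit_univariate_k(x[, c("gene_id", paste0("c", 1:10))], labs, k = 2))
  expect_true("c1" %in% global_keep)
  expect_setequal(res$probabilities$gene_id, labs$gene_id)
  expect_true(all(res$folds$gmean >= 0 & res$folds$gmean <= 1))
})
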