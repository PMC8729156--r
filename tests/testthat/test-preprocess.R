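test_that("minimum-occurrence filter matches the column-sum oracle", {
  x <- toy_matrix(rbind(c(1, 1), c(1, 0), c(0, 0)))
  p <- fit_min_occurrence(x, t = 3)
  expect_false("f1" %in% retained_features(p))  # only 2 positives
  p1 <- fit_min_occurrence(x, t = 1)
  expect_setequal(retained_features(p1), c("f1", "f2"))

  withr::with_seed(9, {
    m <- matrix(rbinom(50 * 20, 1, 0.2), 50, 20)
    xx <- toy_matrix(m)
    got <- retained_features(fit_min_occurrence(xx, t = 4))
    want <- colnames(m <- as.matrix(xx[setdiff(names(xx), "gene_id")]))[colSums(m) >= 4]
    expect_setequal(got, want)
  })
  expect_error(fit_min_occurrence(toy_matrix(cbind(c(0.2, 0.5))), t = 1),
               class = "drinfer_type_error")
})

test_that("correlation filter drops the later member of a correlated pair", {
  withr::with_seed(10, {
    base <- matrix(rnorm(40 * 10), 40, 10)
    base[, 7] <- base[, 2] + rnorm(40, sd = 0.001)  # planted r > 0.999 pair
    x <- toy_matrix(base)
    plan <- fit_correlation_filter(x, cutoff = 0.99)
    kept <- retained_features(plan)
    # oracle: full correlation matrix
    cm <- abs(stats::cor(base))
    expect_gt(cm[2, 7], 0.99)
    expect_true("f2" %in% kept)     # earlier column kept
    expect_false("f7" %in% kept)
    expect_equal(length(kept), 9)
  })

  dup <- toy_matrix(cbind(rnorm(10), rnorm(10)))
  dup$f2 <- dup$f1
  expect_false("f2" %in% retained_features(fit_correlation_filter(dup)))

  orth <- toy_matrix(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_equal(length(retained_features(fit_correlation_filter(orth))), 3)
})

test_that("zero-variance columns warn, correlate as 0, and constants deduplicate", {
  x <- toy_matrix(cbind(rnorm(10), rep(2, 10), rep(2, 10)))
  expect_warning(plan <- fit_correlation_filter(x), "Zero-variance")
  kept <- retained_features(plan)
  expect_true("f2" %in% kept)       # first constant retained
  expect_false("f3" %in% kept)      # duplicated constant dropped
})

test_that("univariate F filter keeps the top-k and matches exhaustive F ranking", {
  labs <- toy_labels(10, 30)
  withr::with_seed(12, {
    m <- matrix(rnorm(40 * 8), 40, 8)
    m[labs$label == "DR", 5] <- m[labs$label == "DR", 5] + 10  # huge effect
    x <- toy_matrix(m, gene_ids = labs$gene_id)
  })
  expect_equal(retained_features(fit_univariate_k(x, labs, k = 1)), "f5")
  # k >= n_features is the identity
  expect_equal(length(retained_features(fit_univariate_k(x, labs, k = 100))), 8)
  # oracle: rank every feature by aov F
  fs <- vapply(setdiff(names(x), "gene_id"), function(f) {
    summary(stats::aov(x[[f]] ~ factor(labs$label)))[[1]]$`F value`[1]
  }, double(1))
  want <- names(sort(fs, decreasing = TRUE))[1:3]
  expect_setequal(retained_features(fit_univariate_k(x, labs, k = 3)), want)
  # constant feature ranks last
  x$f1 <- 1
  kept7 <- retained_features(fit_univariate_k(x, labs, k = 7))
  expect_false("f1" %in% kept7)
  expect_error(fit_univariate_k(x, dplyr::mutate(labs, label = "DR"), k = 2),
               "Both classes")
})

test_that("mixed-matrix plan dispatches by realized kind and unions branches", {
  labs <- toy_labels(6, 14)
  withr::with_seed(13, {
    bin <- matrix(rbinom(20 * 4, 1, 0.5), 20, 4)
    con <- matrix(rnorm(20 * 4), 20, 4)
    # a nominally continuous column realizing only two values -> binary branch
    twoval <- rep(c(0, 1), 10)
    x <- toy_matrix(cbind(bin, con, twoval), gene_ids = labs$gene_id,
                    feature_ids = c(paste0("b", 1:4), paste0("c", 1:4), "tv"))
  })
  plan <- plan_for_dataset(x, labs, t = 3, k = 3, cutoff = 0.99)
  tb <- tidy(plan)
  expect_equal(tb$branch[tb$feature == "tv"], "binary")
  expect_setequal(tb$branch[grepl("^c", tb$feature)], "continuous")

  # oracle: run the branches separately, retained = union
  bin_cols <- c(paste0("b", 1:4), "tv")
  pb <- fit_min_occurrence(x[, c("gene_id", bin_cols)], t = 3)
  pu <- fit_univariate_k(x[, c("gene_id", paste0("c", 1:4))], labs, k = 3)
  pc <- fit_correlation_filter(x[, c("gene_id", retained_features(pu))], 0.99)
  expect_setequal(retained_features(plan),
                  c(retained_features(pb), retained_features(pc)))

  # all-binary matrix: plan equals min-occurrence alone
  xb <- x[, c("gene_id", paste0("b", 1:4))]
  expect_setequal(retained_features(plan_for_dataset(xb, labs, t = 3)),
                  retained_features(fit_min_occurrence(xb, t = 3)))
})

test_that("applying a plan restricts to retained features and never errors on its own matrix", {
  labs <- toy_labels(4, 8)
  withr::with_seed(14, {
    x <- toy_matrix(matrix(rbinom(12 * 5, 1, 0.4), 12, 5), gene_ids = labs$gene_id)
  })
  plan <- plan_for_dataset(x, labs, t = 3)
  out <- apply_plan(plan, x)
  expect_equal(setdiff(names(out), "gene_id"), retained_features(plan))
  expect_error(apply_plan(plan, x[, 1:2][, "gene_id", drop = FALSE]), "lacks")
})
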