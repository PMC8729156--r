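# Pluggable imbalance-aware classifier engines.
#
# The built-in engine ("balanced-bagged-trees" / "balanced-random-forest") is
# a bagging ensemble of decision trees in which every member tree is trained
# on an independent undersample of the training set (all minority instances
# plus an equal-size majority subsample) and on a random feature subspace —
# the balanced-random-forest scheme. "gradient-boosting-xgb" adapts xgboost;
# because boosting has no internal balancing, its training set is
# undersampled once by the evaluation engine. "easy-ensemble" bags boosted
# members, each trained on its own independent undersample.

SUPPORTED_ALGORITHMS <- c("balanced-bagged-trees", "balanced-random-forest",
                          "easy-ensemble", "gradient-boosting-xgb",
                          "gradient-boosting-cat")

#' Classifier specification
#'
#' @param algorithm One of `"balanced-bagged-trees"`,
#'   `"balanced-random-forest"` (aliases for the built-in balanced bagging of
#'   decision trees), `"easy-ensemble"`, `"gradient-boosting-xgb"`, or
#'   `"gradient-boosting-cat"` (recognised but unavailable: no CatBoost R
#'   backend is shipped).
#' @param grid Named list of candidate hyperparameter values, crossed with
#'   the run configuration's `thresholds_set` during inner selection. `NULL`
#'   uses a small per-algorithm default grid.
#' @return An object of class `dr_classifier`.
#' @examples
#' dr_classifier("balanced-random-forest", grid = list(n_trees = c(50, 100)))
#' @export
dr_classifier <- function(algorithm = "balanced-random-forest", grid = NULL) {
  if (!algorithm %in% SUPPORTED_ALGORITHMS) {
    abort(sprintf("Unknown algorithm '%s'. Supported: %s.", algorithm,
                  paste(SUPPORTED_ALGORITHMS, collapse = ", ")))
  }
  if (algorithm == "gradient-boosting-cat") {
    abort("No CatBoost backend is available; use 'gradient-boosting-xgb' instead.")
  }
  if (is.null(grid)) {
    grid <- switch(algorithm,
      "balanced-bagged-trees" = ,
      "balanced-random-forest" = list(n_trees = 100L),
      "easy-ensemble" = list(n_members = 10L, nrounds = 20L),
      "gradient-boosting-xgb" = list(nrounds = 50L, max_depth = 3L)
    )
  }
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid))) {
    abort("`grid` must be a nonempty named list of candidate values.")
  }
  structure(
    list(algorithm = algorithm, grid = grid,
         handles_imbalance = algorithm %in% c("balanced-bagged-trees",
                                              "balanced-random-forest",
                                              "easy-ensemble")),
    class = "dr_classifier"
  )
}

# Internally features are renamed V1..Vp so non-syntactic ids (GO terms,
# pathway ids) survive the formula interfaces.
encode_features <- function(m) {
  map <- setNames(colnames(m), paste0("V", seq_len(ncol(m))))
  colnames(m) <- names(map)
  list(m = m, map = map)
}

undersample_idx <- function(y, seed) {
  pos <- which(y == DR_POS)
  neg <- which(y == DR_NEG)
  withr::with_seed(seed, {
    neg_keep <- if (length(neg) > length(pos)) sample(neg, length(pos)) else neg
  })
  sort(c(pos, neg_keep))
}

fit_brf <- function(m, y, params, seed) {
  n_trees <- params$n_trees %||% 100L
  min_node <- params$min_node %||% 5L
  cp <- params$cp %||% 0.01
  p <- ncol(m)
  n_feat <- max(1L, params$mtry %||% ceiling(sqrt(p)))
  trees <- vector("list", n_trees)
  feats <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    s <- substream(seed, 7000L + b)
    idx <- undersample_idx(y, s)
    withr::with_seed(s + 1L, {
      fs <- sample(seq_len(p), min(n_feat, p))
    })
    df <- as.data.frame(m[idx, fs, drop = FALSE])
    df$.y <- factor(y[idx], levels = c(DR_NEG, DR_POS))
    trees[[b]] <- rpart::rpart(
      .y ~ ., data = df, method = "class",
      control = rpart::rpart.control(minbucket = min_node, cp = cp,
                                     maxsurrogate = 0, maxcompete = 0, xval = 0)
    )
    feats[[b]] <- fs
  }
  list(trees = trees, feats = feats)
}

predict_brf <- function(fit, m) {
  probs <- vapply(seq_along(fit$trees), function(b) {
    df <- as.data.frame(m[, fit$feats[[b]], drop = FALSE])
    pr <- predict(fit$trees[[b]], newdata = df, type = "prob")
    if (DR_POS %in% colnames(pr)) pr[, DR_POS] else rep(0, nrow(m))
  }, double(nrow(m)))
  if (nrow(m) == 1L) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}

fit_xgb_one <- function(m, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(m, label = as.integer(y == DR_POS))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth %||% 3L,
                  eta = params$eta %||% 0.3,
                  nthread = 1L, seed = seed),
    data = dtrain,
    nrounds = params$nrounds %||% 50L,
    verbose = 0
  )
}

fit_easy <- function(m, y, params, seed) {
  n_members <- params$n_members %||% 10L
  members <- lapply(seq_len(n_members), function(b) {
    s <- substream(seed, 9000L + b)
    idx <- undersample_idx(y, s)
    fit_xgb_one(m[idx, , drop = FALSE], y[idx], params, s)
  })
  list(members = members)
}

#' Fit a classifier on a feature matrix
#'
#' Low-level fitting entry used by the nested-CV engine; exposed so that
#' importance calculations can refit the chosen configuration on all genes.
#'
#' @param spec A [dr_classifier()].
#' @param x Feature tibble (already preprocessed).
#' @param labels Labels tibble covering `x`'s genes.
#' @param params Named list: one hyperparameter configuration.
#' @param seed Integer seed.
#' @return A `dr_model`.
#' @export
fit_model <- function(spec, x, labels, params = list(), seed = 42) {
  stopifnot(inherits(spec, "dr_classifier"))
  check_labels(labels, require_both_classes = TRUE)
  m0 <- fm_matrix(x)
  if (ncol(m0) == 0L) abort("Cannot fit a model on zero features.")
  y <- labels$label[match(rownames(m0), labels$gene_id)]
  if (anyNA(y)) abort("Every gene in `x` needs a label.")
  enc <- encode_features(m0)
  fit <- switch(spec$algorithm,
    "balanced-bagged-trees" = ,
    "balanced-random-forest" = fit_brf(enc$m, y, params, seed),
    "easy-ensemble" = fit_easy(enc$m, y, params, seed),
    "gradient-boosting-xgb" = fit_xgb_one(enc$m, y, params, seed)
  )
  structure(list(spec = spec, params = params, fit = fit, feature_map = enc$map,
                 seed = seed),
            class = "dr_model")
}

#' Predict minority-class (DR) probabilities
#'
#' @param object A `dr_model`.
#' @param x Feature tibble with (at least) the model's features.
#' @param ... Unused.
#' @return Named numeric vector of DR probabilities, one per gene of `x`.
#' @export
predict.dr_model <- function(object, x, ...) {
  m <- fm_matrix(x)[, unname(object$feature_map), drop = FALSE]
  colnames(m) <- names(object$feature_map)
  p <- switch(object$spec$algorithm,
    "balanced-bagged-trees" = ,
    "balanced-random-forest" = predict_brf(object$fit, m),
    "easy-ensemble" = {
      pr <- vapply(object$fit$members, function(mm) {
        as.numeric(predict(mm, m))
      }, double(nrow(m)))
      if (nrow(m) == 1L) pr <- matrix(pr, nrow = 1L)
      rowMeans(pr)
    },
    "gradient-boosting-xgb" = as.numeric(predict(object$fit, m))
  )
  setNames(p, rownames(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
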