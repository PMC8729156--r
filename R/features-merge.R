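# Whole-dataset assembly: merging heterogeneous feature tables, 5-nearest-
# neighbour imputation of the resulting gaps, and the complete-case
# intersection alternative.

#' Merge feature tables over the union of genes
#'
#' Instances are unioned, feature columns concatenated. A gene missing from a
#' source table gets `NA` across that table's columns (the missing mask that
#' imputation or intersection later resolves). Feature ids are prefixed with
#' the source dataset's name (`name.feature`) so they are globally unique.
#'
#' @param matrices Named list of feature tibbles.
#' @return A feature tibble over the union of gene ids (sorted), with
#'   `sum(ncol parts)` feature columns.
#' @examples
#' a <- tibble::tibble(gene_id = c("g1", "g2"), f1 = c(0, 1))
#' b <- tibble::tibble(gene_id = c("g2", "g3"), f1 = c(0.5, 0.7))
#' merge_datasets(list(A = a, B = b))
#' @export
merge_datasets <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) > 0)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    abort("`matrices` must be a named list; names prefix the feature ids.")
  }
  genes <- sort(unique(unlist(lapply(matrices, function(x) x$gene_id))))
  parts <- imap(matrices, function(x, nm) {
    m <- fm_matrix(x)
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                  dimnames = list(genes, colnames(m)))
    out[rownames(m), ] <- m
    out
  })
  if (anyDuplicated(unlist(lapply(parts, colnames)))) {
    abort("Feature ids are not globally unique after prefixing.")
  }
  fm_tibble(do.call(cbind, parts))
}

# Pairwise mean squared difference over shared known features; Inf where two
# genes share no known feature.
mean_sq_diff <- function(m) {
  B <- !is.na(m)
  A <- m
  A[!B] <- 0
  P <- A * A
  Bn <- B * 1
  shared <- Bn %*% t(Bn)
  ss <- P %*% t(Bn) + Bn %*% t(P) - 2 * (A %*% t(A))
  d <- ss / shared
  d[shared == 0] <- Inf
  d
}

#' Impute missing cells by 5 nearest neighbours in the training set
#'
#' For a gene G missing feature F, the neighbours are the `k` training-set
#' genes with a known value of F that are nearest to G, where nearness is the
#' mean squared difference over the features known in both genes (the mean —
#' rather than the sum — keeps genes with different missingness comparable).
#' Continuous features are imputed by the neighbour mean, binary features by
#' the neighbour mode (ties impute 0: the majority value of sparse binary
#' annotations is absence). Fewer than `k` eligible neighbours: all available
#' are used, with a warning; none: the column's training mean/mode, with a
#' warning. Genes with no missing values pass through unchanged.
#'
#' Imputation statistics come from training instances only, so the
#' transformation can be fitted inside a cross-validation training fold and
#' applied to held-out genes without leakage.
#'
#' @param x Feature tibble (typically a [merge_datasets()] result).
#' @param train_ids Gene ids allowed to serve as neighbours / statistics
#'   donors; defaults to all genes.
#' @param k Number of neighbours (default 5).
#' @return The feature tibble with every `NA` imputed.
#' @export
impute_5nn <- function(x, train_ids = x$gene_id, k = 5) {
  m <- fm_matrix(x)
  if (!all(train_ids %in% rownames(m))) {
    abort("`train_ids` must be a subset of the gene ids.")
  }
  if (!anyNA(m)) return(x)
  kinds <- feature_kinds(x)
  d <- mean_sq_diff(m)
  train <- rownames(m) %in% train_ids
  warned_few <- FALSE; warned_none <- FALSE

  impute_value <- function(vals, kind) {
    if (kind == "binary") {
      if (mean(vals) > 0.5) 1 else 0  # tie (0.5) imputes 0
    } else mean(vals)
  }

  for (j in seq_len(ncol(m))) {
    miss <- which(is.na(m[, j]))
    if (length(miss) == 0L) next
    donors <- which(train & !is.na(m[, j]))
    col_known <- m[donors, j]
    for (i in miss) {
      cand <- setdiff(donors, i)
      dist_i <- d[i, cand]
      cand <- cand[is.finite(dist_i)]
      dist_i <- dist_i[is.finite(dist_i)]
      if (length(cand) == 0L) {
        if (length(col_known) == 0L) {
          abort(sprintf("No training value available to impute feature '%s'.",
                        colnames(m)[j]))
        }
        if (!warned_none) {
          warn("Gene(s) with no eligible neighbours; used column-wise training mean/mode.")
          warned_none <- TRUE
        }
        m[i, j] <- impute_value(col_known, kinds[j])
        next
      }
      if (length(cand) < k && !warned_few) {
        warn("Fewer than k eligible neighbours for some cells; used all available.")
        warned_few <- TRUE
      }
      ord <- order(dist_i, rownames(m)[cand])  # deterministic tie-break by id
      nn <- cand[ord][seq_len(min(k, length(cand)))]
      m[i, j] <- impute_value(m[nn, j], kinds[j])
    }
  }
  fm_tibble(m)
}

#' Keep only complete-case genes
#'
#' The intersection alternative to imputation: retains the genes observed in
#' every merged source, i.e. the rows with zero missing cells.
#'
#' @param x Feature tibble.
#' @return The rows of `x` with no `NA`.
#' @export
intersect_complete <- function(x) {
  m <- fm_matrix(x)
  keep <- rowSums(is.na(m)) == 0
  x[keep, , drop = FALSE]
}
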