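# Internal helpers shared across modules.

#' Check a labels table
#'
#' Validates the canonical gene-label table: a data frame with character
#' columns `gene_id` (unique) and `label` (values `"DR"` / `"NotDR"`).
#'
#' @param labels A data frame with columns `gene_id` and `label`.
#' @param require_both_classes Require both classes to be present?
#' @return The labels, invisibly, as a tibble.
#' @keywords internal
check_labels <- function(labels, require_both_classes = FALSE) {
  if (!is.data.frame(labels) || !all(c("gene_id", "label") %in% names(labels))) {
    abort("`labels` must be a data frame with columns `gene_id` and `label`.")
  }
  if (anyDuplicated(labels$gene_id)) {
    abort("Duplicate gene ids in `labels`.")
  }
  bad <- setdiff(unique(labels$label), c(DR_POS, DR_NEG))
  if (length(bad)) {
    abort(sprintf("Unknown labels: %s (expected 'DR'/'NotDR').",
                  paste(bad, collapse = ", ")))
  }
  if (require_both_classes && length(unique(labels$label)) < 2L) {
    abort("Both classes ('DR' and 'NotDR') must be present.")
  }
  invisible(as_tibble(labels))
}

#' Convert a feature table to a numeric matrix
#'
#' Feature tables carry genes in a `gene_id` column and one numeric column per
#' feature; `NA` marks missing values.
#'
#' @param x Feature table.
#' @return Numeric matrix with gene ids as rownames.
#' @keywords internal
fm_matrix <- function(x) {
  stopifnot(is.data.frame(x), "gene_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

#' Rebuild a feature table from a matrix
#' @keywords internal
fm_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

#' Per-feature kind inference
#'
#' A column is `binary` iff its non-missing values are a subset of \{0, 1\};
#' everything else is `continuous`. Matches the file-reader inference rule.
#'
#' @param x Feature table.
#' @return Named character vector, one of `"binary"`/`"continuous"` per feature.
#' @export
feature_kinds <- function(x) {
  m <- fm_matrix(x)
  kinds <- apply(m, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L || all(v %in% c(0, 1))) "binary" else "continuous"
  })
  setNames(as.character(kinds), colnames(m))
}

#' Deterministic sub-stream seed
#'
#' One global integer seed drives every generator; each artifact kind draws
#' from a sub-stream derived deterministically from it, so datasets of
#' different types over the same genes are jointly reproducible.
#'
#' @keywords internal
substream <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}

#' Geometric-mean-style affine rescale to [0, 100]
#' @keywords internal
rescale_0_100 <- function(raw) {
  rng <- range(raw)
  if (diff(rng) == 0) {
    warn("Constant raw importance vector; all scaled scores set to 0.")
    return(rep(0, length(raw)))
  }
  100 * (raw - rng[1]) / (rng[2] - rng[1])
}
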