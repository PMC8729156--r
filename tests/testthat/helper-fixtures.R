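# Shared in-code fixtures; everything is generated, nothing read from disk.

library(dplyr)

toy_labels <- function(n_dr = 3, n_not = 7) {
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n_dr + n_not)),
    label = c(rep("DR", n_dr), rep("NotDR", n_not))
  )
}

# small feature tibble from a matrix-like spec
toy_matrix <- function(values, gene_ids = NULL, feature_ids = NULL) {
  m <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(feature_ids)) feature_ids <- sprintf("f%d", seq_len(ncol(m)))
  dimnames(m) <- list(gene_ids, feature_ids)
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# a random small directed graph (possibly cyclic) over n named nodes
random_digraph <- function(n, p = 0.25) {
  nodes <- sprintf("n%d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p, ]
  igraph::graph_from_data_frame(pairs, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

# Independent oracle for influence: explicit reachability enumeration by DFS
# over the edge list, no igraph reachability helpers.
oracle_influence <- function(graph, reference) {
  el <- igraph::as_data_frame(graph, what = "edges")
  nodes <- igraph::V(graph)$name
  reach_set <- function(start, edges) {
    seen <- character(0); stack <- start
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, edges$to[edges$from == v])
    }
    seen
  }
  indeg <- vapply(nodes, function(v) sum(el$to == v), integer(1))
  sources <- nodes[indeg == 0]
  if (length(sources) == 0) sources <- nodes
  el_minus <- el[el$from != reference & el$to != reference, ]
  targets <- setdiff(nodes, reference)
  ref_reach <- reach_set(reference, el)
  vapply(targets, function(t) {
    s_t <- sum(vapply(sources, function(s) t %in% reach_set(s, el), logical(1)))
    if (s_t == 0 || !(t %in% ref_reach)) return(0)
    s_m <- sum(vapply(setdiff(sources, reference), function(s) {
      t %in% reach_set(s, el_minus)
    }, logical(1)))
    1 - s_m / s_t
  }, double(1))
}

# Brute-force 5NN imputation oracle: exhaustive distance table, no sharing of
# code with impute_5nn().
oracle_impute <- function(x, train_ids, k = 5) {
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  kinds <- apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0 || all(v %in% c(0, 1))) "binary" else "continuous"
  })
  out <- m
  for (g in rownames(m)) for (f in colnames(m)) {
    if (!is.na(m[g, f])) next
    cand <- setdiff(intersect(train_ids, rownames(m)[!is.na(m[, f])]), g)
    d <- vapply(cand, function(h) {
      shared <- !is.na(m[g, ]) & !is.na(m[h, ])
      if (!any(shared)) return(Inf)
      mean((m[g, shared] - m[h, shared])^2)
    }, double(1))
    cand <- cand[is.finite(d)]; d <- d[is.finite(d)]
    if (length(cand) == 0) {
      vals <- m[intersect(train_ids, rownames(m)), f]
      vals <- vals[!is.na(vals)]
    } else {
      nn <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
      vals <- m[nn, f]
    }
    out[g, f] <- if (kinds[f] == "binary") {
      if (mean(vals) > 0.5) 1 else 0
    } else mean(vals)
  }
  out
}
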