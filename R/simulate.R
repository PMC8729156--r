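# Synthetic-data module: generators for labels, annotation structures, graphs
# and feature matrices with the statistical structure the analysis assumes.
# Every generator draws from a sub-stream derived from the one config seed, so
# artifacts of different kinds over the same genes are jointly reproducible.

SUBSTREAM_LABELS <- 1L
SUBSTREAM_BINARY <- 2L
SUBSTREAM_DAG <- 3L
SUBSTREAM_PATHWAY <- 4L
SUBSTREAM_PPI <- 5L
SUBSTREAM_CONTINUOUS <- 6L

#' Simulate a labelled gene set
#'
#' Generates `n_genes` synthetic gene identifiers and assigns exactly
#' `round(minority_fraction * n_genes)` of them the minority `"DR"` label; the
#' rest are `"NotDR"`. The default 1:10 ratio mirrors the imbalance of curated
#' ageing-gene collections, where DR-annotated genes are roughly tenfold rarer
#' than other ageing-related genes.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene_id` and `label`.
#' @examples
#' simulate_labels(sim_config(n_genes = 100, seed = 7)) |> head()
#' @export
simulate_labels <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  n_min <- as.integer(round(config$minority_fraction * n))
  ids <- sprintf("g%0*d", nchar(n), seq_len(n))
  withr::with_seed(substream(config$seed, SUBSTREAM_LABELS), {
    minority <- sample(ids, n_min)
  })
  tibble(
    gene_id = ids,
    label = ifelse(ids %in% minority, DR_POS, DR_NEG)
  )
}

#' Simulate a sparse binary annotation matrix with planted enrichment
#'
#' Emulates pathway-membership / GO-style binary matrices. Cells are Bernoulli
#' draws: non-planted features use `base_positive_rate` in both classes;
#' planted features use `min(1, base_positive_rate * enrichment_odds)` in the
#' minority class, so the enrichment odds control how strongly the planted
#' subset separates the classes.
#'
#' @param labels A labels tibble from [simulate_labels()].
#' @param config A [sim_config()].
#' @return A list with `matrix` (feature table: `gene_id` + binary columns)
#'   and `planted` (character vector of planted feature ids).
#' @export
simulate_binary_matrix <- function(labels, config) {
  validate_sim_config(config)
  check_labels(labels)
  if (nrow(labels) == 0L) abort("`labels` must be nonempty.")
  p <- config$n_binary_features
  feat <- sprintf("bf%0*d", nchar(max(p, 1L)), seq_len(p))
  planted <- head(feat, config$n_enriched_features)
  minority <- labels$label == DR_POS
  p_enriched <- min(1, config$base_positive_rate * config$enrichment_odds)
  withr::with_seed(substream(config$seed, SUBSTREAM_BINARY), {
    m <- matrix(rbinom(nrow(labels) * p, 1L, config$base_positive_rate),
                nrow = nrow(labels), ncol = p,
                dimnames = list(labels$gene_id, feat))
    if (length(planted) && any(minority)) {
      m[minority, planted] <- rbinom(sum(minority) * length(planted), 1L, p_enriched)
    }
  })
  list(matrix = fm_tibble(m), planted = planted)
}

#' Simulate a rooted annotation DAG with direct gene annotations
#'
#' Builds a layered random DAG with a single root (layer 0). Each node in
#' layer `i` has at least one parent in layer `i - 1`, so every term has a
#' directed path to the root — the structural property the true-path rule
#' (a gene annotated to a term is implicitly annotated to all its ancestors)
#' relies on. Direct annotations are assigned to random (mostly deep) terms
#' and are returned *unpropagated*; ancestor closure is the feature builders'
#' job.
#'
#' @param labels A labels tibble.
#' @param config A [sim_config()]; `dag_depth` and `dag_branching` set the
#'   shape.
#' @return An object of class `dr_dag`: list with `terms`, `edges` (tibble
#'   `child`, `parent`), `root`, and `annotations` (tibble `gene_id`,
#'   `term_id`).
#' @export
simulate_dag_annotations <- function(labels, config) {
  validate_sim_config(config)
  check_labels(labels)
  depth <- config$dag_depth
  b <- config$dag_branching
  layers <- vector("list", depth + 1L)
  layers[[1]] <- "T_root"
  for (d in seq_len(depth)) {
    layers[[d + 1L]] <- sprintf("T_%d_%d", d, seq_len(b^min(d, 4L)))
  }
  terms <- unlist(layers)
  withr::with_seed(substream(config$seed, SUBSTREAM_DAG), {
    edges <- purrr::map(seq_len(depth), function(d) {
      children <- layers[[d + 1L]]
      parents <- layers[[d]]
      # every child gets one guaranteed parent in the layer above, plus an
      # occasional second parent to make it a DAG rather than a tree
      first <- sample(parents, length(children), replace = TRUE)
      extra <- purrr::map2(children, first, function(ch, pa) {
        pool <- setdiff(parents, pa)
        if (length(pool) && runif(1) < 0.3) {
          tibble(child = ch, parent = sample(pool, 1L))
        } else NULL
      })
      bind_rows(tibble(child = children, parent = first), bind_rows(extra))
    }) |> bind_rows()
    deep_terms <- unlist(layers[-1])
    ann <- purrr::map(labels$gene_id, function(g) {
      k <- sample(1:3, 1L)
      tibble(gene_id = g, term_id = sample(deep_terms, min(k, length(deep_terms))))
    }) |> bind_rows()
  })
  structure(
    list(terms = terms, edges = edges, root = "T_root",
         annotations = dplyr::distinct(ann)),
    class = "dr_dag"
  )
}

#' Simulate a directed pathway graph
#'
#' Generates a directed graph over `graph_n_nodes` pathway members. In
#' acyclic mode (the default) edges only point from earlier to later nodes in
#' a random order, which guarantees at least one zero-in-degree source node —
#' the anchor of the upstream-reachability influence score.
#'
#' @param config A [sim_config()].
#' @param acyclic Generate a DAG (default) or allow cycles?
#' @param node_ids Optional node names (length `graph_n_nodes`); defaults to
#'   `p1`, `p2`, ....
#' @param stream_offset Integer offset added to the pathway sub-stream so a
#'   collection of pathways over the same config is jointly reproducible yet
#'   mutually distinct.
#' @return A directed `igraph` with a `name` vertex attribute.
#' @export
simulate_pathway_graph <- function(config, acyclic = TRUE, node_ids = NULL,
                                   stream_offset = 0L) {
  validate_sim_config(config)
  n <- config$graph_n_nodes
  if (is.null(node_ids)) node_ids <- sprintf("p%d", seq_len(n))
  stopifnot(length(node_ids) == n)
  withr::with_seed(substream(config$seed, SUBSTREAM_PATHWAY + 100L * stream_offset), {
    ord <- sample(node_ids)
    pairs <- t(utils::combn(n, 2L))
    keep <- runif(nrow(pairs)) < config$graph_edge_density
    pairs <- pairs[keep, , drop = FALSE]
    if (!acyclic && nrow(pairs)) {
      flip <- runif(nrow(pairs)) < 0.5
      pairs[flip, ] <- pairs[flip, c(2L, 1L)]
    }
  })
  el <- cbind(ord[pairs[, 1L]], ord[pairs[, 2L]])
  g <- igraph::graph_from_data_frame(
    as.data.frame(el, stringsAsFactors = FALSE) |> setNames(c("from", "to")),
    directed = TRUE,
    vertices = data.frame(name = node_ids)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Simulate an undirected PPI network
#'
#' Preferential-attachment (Barabási–Albert) growth imitates the
#' hub-dominated degree distributions of physical interaction networks.
#' Nodes are the labelled genes plus `extra_nodes` unlabelled neighbours,
#' attached in random order; loops and repeated edges are removed, so the
#' result is a simple graph.
#'
#' @param labels A labels tibble.
#' @param config A [sim_config()].
#' @param extra_nodes Number of unlabelled interactor nodes to add.
#' @param edges_per_node New edges per added node in the attachment process.
#' @return An undirected simple `igraph`; vertices carry a `label` attribute
#'   (`"DR"`, `"NotDR"`, or `NA` for unlabelled interactors).
#' @export
simulate_ppi_network <- function(labels, config, extra_nodes = 20L,
                                 edges_per_node = 2L) {
  validate_sim_config(config)
  check_labels(labels)
  ids <- c(labels$gene_id, sprintf("x%d", seq_len(extra_nodes)))
  withr::with_seed(substream(config$seed, SUBSTREAM_PPI), {
    ord <- sample(ids)
    g <- igraph::sample_pa(length(ids), m = edges_per_node, directed = FALSE)
  })
  igraph::V(g)$name <- ord
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  lab <- labels$label[match(igraph::V(g)$name, labels$gene_id)]
  igraph::V(g)$label_class <- lab
  g
}

#' Simulate a continuous feature matrix with planted class signal
#'
#' Standard-normal features; the first `n_planted_continuous` columns have
#' their minority-class mean shifted by `continuous_effect_size` standard
#' deviations, emulating expression-style matrices whose class signal the
#' univariate F filter should recover.
#'
#' @param labels A labels tibble.
#' @param config A [sim_config()].
#' @return A list with `matrix` (feature table) and `planted` (feature ids).
#' @export
simulate_continuous_matrix <- function(labels, config) {
  validate_sim_config(config)
  check_labels(labels)
  if (nrow(labels) == 0L) abort("`labels` must be nonempty.")
  p <- config$n_continuous_features
  feat <- sprintf("cf%0*d", nchar(max(p, 1L)), seq_len(p))
  planted <- head(feat, config$n_planted_continuous)
  minority <- labels$label == DR_POS
  withr::with_seed(substream(config$seed, SUBSTREAM_CONTINUOUS), {
    m <- matrix(rnorm(nrow(labels) * p), nrow = nrow(labels),
                dimnames = list(labels$gene_id, feat))
    if (length(planted)) {
      m[minority, planted] <- m[minority, planted] + config$continuous_effect_size
    }
  })
  list(matrix = fm_tibble(m), planted = planted)
}
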