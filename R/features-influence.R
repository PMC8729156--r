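# Pathway-graph influence scoring: how strongly one node controls upstream
# access to the other nodes of a directed pathway graph.

#' Influence of a reference node on every other node of a pathway graph
#'
#' For a directed pathway graph, let the *sources* S be the zero-in-degree
#' nodes (if the graph has none — e.g. it is fully cyclic — every node counts
#' as a source). For a target `t`, `S(t)` is the set of sources from which
#' `t` is reachable and `S_-r(t)` the same set after deleting the reference
#' node `r` and its incident edges. The influence of `r` on `t` is
#'
#' \deqn{1 - |S_{-r}(t)| / |S(t)|}
#'
#' i.e. the fraction of `t`'s upstream routes that pass through `r`: 1 when
#' `t` can be reached only via `r`, shrinking towards 0 as independent
#' upstream paths appear, and exactly 0 when `t` is not downstream of `r` at
#' all (targets not reachable from the reference receive 0 regardless of the
#' ratio).
#'
#' @param graph Directed `igraph` with named vertices.
#' @param reference Name of the reference node (must be in the graph).
#' @return A tibble `node`, `influence` over all nodes except the reference;
#'   influence values lie in \[0, 1\].
#' @examples
#' g <- igraph::graph_from_literal(r --+ a, a --+ b)
#' influence_profile(g, "r")
#' @export
influence_profile <- function(graph, reference) {
  stopifnot(igraph::is_directed(graph))
  nodes <- igraph::V(graph)$name
  if (!reference %in% nodes) {
    abort(sprintf("Reference node '%s' is not in the graph.", reference))
  }
  targets <- setdiff(nodes, reference)
  if (length(targets) == 0L) {
    return(tibble(node = character(), influence = double()))
  }
  sources <- nodes[igraph::degree(graph, mode = "in") == 0]
  if (length(sources) == 0L) sources <- nodes

  reach_from <- function(g, from_set) {
    # targets reachable from each node of from_set, as a node x target logical
    if (length(from_set) == 0L) {
      return(matrix(FALSE, 0L, length(targets), dimnames = list(NULL, targets)))
    }
    d <- igraph::distances(g, v = from_set, to = intersect(targets, igraph::V(g)$name),
                           mode = "out")
    out <- matrix(FALSE, length(from_set), length(targets),
                  dimnames = list(from_set, targets))
    out[, colnames(d)] <- is.finite(d)
    out
  }

  full <- reach_from(graph, sources)
  gm <- igraph::delete_vertices(graph, reference)
  reduced <- reach_from(gm, setdiff(sources, reference))
  downstream <- reach_from(graph, reference)[1, ]

  s_t <- colSums(full)
  s_minus <- colSums(reduced)
  infl <- ifelse(s_t == 0, 0, 1 - s_minus / s_t)
  infl[!downstream] <- 0
  tibble(node = targets, influence = as.numeric(infl))
}

#' Pathway-influence feature matrix
#'
#' One continuous column per pathway. For a gene inside a pathway, the cell
#' is the mean influence the gene exerts over all other nodes of that
#' pathway's graph; genes absent from the pathway (and single-node pathways,
#' which have no targets) get 0.
#'
#' @param pathway_graphs Named list of directed `igraph` objects.
#' @param genes Labels tibble defining instance rows.
#' @return A continuous feature tibble (`gene_id` + one column per pathway).
#' @export
influence_matrix <- function(pathway_graphs, genes) {
  stopifnot(is.list(pathway_graphs), !is.null(names(pathway_graphs)))
  ids <- genes$gene_id
  m <- matrix(0, nrow = length(ids), ncol = length(pathway_graphs),
              dimnames = list(ids, names(pathway_graphs)))
  for (pw in names(pathway_graphs)) {
    g <- pathway_graphs[[pw]]
    members <- intersect(ids, igraph::V(g)$name)
    for (gene in members) {
      prof <- influence_profile(g, gene)
      if (nrow(prof)) m[gene, pw] <- mean(prof$influence)
    }
  }
  fm_tibble(m)
}
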