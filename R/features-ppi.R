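# PPI network feature builders: sliced adjacency matrix and the 18 graph
# measures (standard centralities via igraph, the less common ones computed
# here from their literature definitions).

#' Sliced PPI adjacency feature matrix
#'
#' Rows are the labelled genes present in the network; columns are those same
#' genes plus every unlabelled node directly interacting with at least one
#' labelled gene. A cell is 1 iff the row gene and column node share an edge.
#'
#' @param net Undirected simple `igraph` (see [simulate_ppi_network()] or
#'   [read_edge_list()]).
#' @param genes Labels tibble.
#' @return A binary feature tibble.
#' @export
adjacency_features <- function(net, genes) {
  stopifnot(!igraph::is_directed(net))
  nodes <- igraph::V(net)$name
  rows <- intersect(genes$gene_id, nodes)
  if (length(rows) == 0L) {
    return(tibble(gene_id = character(0)))
  }
  adj <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  adj[adj > 0] <- 1
  nb_of_labeled <- colnames(adj)[colSums(adj[rows, , drop = FALSE]) > 0]
  cols <- union(rows, setdiff(nb_of_labeled, genes$gene_id))
  cols <- c(sort(intersect(cols, genes$gene_id)), sort(setdiff(cols, genes$gene_id)))
  m <- adj[rows, cols, drop = FALSE]
  storage.mode(m) <- "double"
  fm_tibble(m)
}

# --- measures computed from literature definitions ------------------------

# Leverage centrality: mean over neighbours u of (k_v - k_u)/(k_v + k_u).
measure_leverage <- function(nbrs, deg) {
  vapply(seq_along(deg), function(i) {
    if (deg[i] == 0) return(0)
    ku <- deg[nbrs[[i]]]
    mean((deg[i] - ku) / (deg[i] + ku))
  }, double(1))
}

# Markov centrality: n_c / sum_j MFPT(j -> v) for a random walk on the
# node's connected component (component size n_c); nodes in components of
# size 1 get 0.
measure_markov <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) < 2L) next
    sub <- igraph::induced_subgraph(g, idx)
    A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    P <- A / rowSums(A)
    nc <- length(idx)
    for (v in seq_len(nc)) {
      # mean first-passage times into v: (I - P[-v,-v]) m = 1
      m <- solve(diag(nc - 1L) - P[-v, -v, drop = FALSE], rep(1, nc - 1L))
      out[idx[v]] <- nc / sum(m)
    }
  }
  out
}

# Maximum neighbourhood component: size of the largest connected component
# of the subgraph induced by the open neighbourhood of v.
measure_mnc <- function(g, nbrs) {
  vapply(seq_along(nbrs), function(i) {
    if (length(nbrs[[i]]) == 0L) return(0)
    sub <- igraph::induced_subgraph(g, nbrs[[i]])
    max(igraph::components(sub)$csize)
  }, double(1))
}

# Laplacian centrality (unweighted closed form): drop in Laplacian energy
# when v is removed = d_v^2 + d_v + 2 * sum of neighbour degrees.
measure_laplacian <- function(nbrs, deg) {
  vapply(seq_along(deg), function(i) {
    deg[i]^2 + deg[i] + 2 * sum(deg[nbrs[[i]]])
  }, double(1))
}

# Diffusion degree: d_v plus the summed degrees of v's neighbours
# (propagation-probability factor fixed at 1; stated in the docs).
measure_diffusion <- function(nbrs, deg) {
  vapply(seq_along(deg), function(i) deg[i] + sum(deg[nbrs[[i]]]), double(1))
}

# Semilocal centrality: C(v) = sum_{u in N(v)} Q(u), Q(u) = sum_{w in N(u)}
# N2(w), with N2(w) the number of nodes within two steps of w (w excluded).
measure_semilocal <- function(g, nbrs) {
  n2 <- vapply(igraph::ego(g, order = 2), length, integer(1)) - 1L
  q <- vapply(seq_along(nbrs), function(i) sum(n2[nbrs[[i]]]), double(1))
  vapply(seq_along(nbrs), function(i) sum(q[nbrs[[i]]]), double(1))
}

# Geodesic k-path centrality: number of nodes within geodesic distance k
# (default 3) of v, v excluded.
measure_geokpath <- function(g, k = 3) {
  vapply(igraph::ego(g, order = k), length, integer(1)) - 1L
}

# Lobby index: largest l such that v has at least l neighbours of degree >= l
# (an h-index over neighbour degrees).
measure_lobby <- function(nbrs, deg) {
  vapply(seq_along(deg), function(i) {
    ku <- sort(deg[nbrs[[i]]], decreasing = TRUE)
    if (length(ku) == 0L) return(0)
    sum(ku >= seq_along(ku))
  }, double(1))
}

# Topological coefficient: T(v) = mean_u J(v, u) / k_v over nodes u != v
# sharing at least one neighbour with v, where J counts shared neighbours
# plus 1 if u and v are adjacent; 0 for degree < 1 or no sharing partners.
measure_topological <- function(g, nbrs, deg) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  shared <- A %*% A  # shared-neighbour counts
  vapply(seq_len(nrow(A)), function(i) {
    if (deg[i] == 0) return(0)
    partners <- which(shared[i, ] > 0)
    partners <- setdiff(partners, i)
    if (length(partners) == 0L) return(0)
    j <- shared[i, partners] + A[i, partners]
    mean(j) / deg[i]
  }, double(1))
}

#' Eighteen per-gene PPI graph measures
#'
#' Computes, for every labelled gene present in the network, the feature set:
#' degree, closeness, betweenness (unnormalized pair counts), eigenvector
#' centrality, eccentricity, k-core number, local clustering coefficient,
#' topological coefficient, leverage, Markov, maximum-neighbourhood-component,
#' Laplacian, diffusion-degree, semilocal, subgraph and geodesic k-path
#' (k = 3) centralities, the lobby index, and the DR-ratio — the fraction of
#' a gene's direct neighbours that carry the minority `"DR"` label (0 for
#' isolated nodes).
#'
#' Conventions for degenerate nodes: isolated nodes get 0 for clustering,
#' closeness, leverage, topological coefficient and DR-ratio; Markov
#' centrality is 0 in singleton components. Closeness and eccentricity are
#' computed within a node's connected component.
#'
#' @param net Undirected simple `igraph`.
#' @param genes Labels tibble; genes absent from the network are dropped with
#'   a warning.
#' @return A continuous feature tibble with 18 columns.
#' @export
graph_measures <- function(net, genes) {
  check_labels(genes)
  nodes <- igraph::V(net)$name
  missing <- setdiff(genes$gene_id, nodes)
  if (length(missing)) {
    warn(sprintf("%d genes absent from the network were dropped.", length(missing)))
  }
  keep <- genes |> filter(.data$gene_id %in% nodes)

  deg <- igraph::degree(net)
  nbrs <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  clo <- suppressWarnings(igraph::closeness(net))
  clo[!is.finite(clo)] <- 0
  ecc <- igraph::eccentricity(net)

  dr_nodes <- genes$gene_id[genes$label == DR_POS]
  is_dr <- nodes %in% dr_nodes
  dr_ratio <- vapply(seq_along(deg), function(i) {
    if (deg[i] == 0) return(0)
    mean(is_dr[nbrs[[i]]])
  }, double(1))

  m <- cbind(
    degree = as.numeric(deg),
    closeness = as.numeric(clo),
    betweenness = as.numeric(igraph::betweenness(net)),
    eigenvector = as.numeric(igraph::eigen_centrality(net)$vector),
    eccentricity = as.numeric(ecc),
    kcore = as.numeric(igraph::coreness(net)),
    clustering = igraph::transitivity(net, type = "local", isolates = "zero"),
    topological = measure_topological(net, nbrs, deg),
    leverage = measure_leverage(nbrs, deg),
    markov = measure_markov(net),
    mnc = measure_mnc(net, nbrs),
    laplacian = measure_laplacian(nbrs, deg),
    diffusion = measure_diffusion(nbrs, deg),
    semilocal = measure_semilocal(net, nbrs),
    subgraph = as.numeric(igraph::subgraph_centrality(net)),
    geokpath = as.numeric(measure_geokpath(net)),
    lobby = measure_lobby(nbrs, deg),
    dr_ratio = dr_ratio
  )
  rownames(m) <- nodes
  fm_tibble(m[keep$gene_id, , drop = FALSE])
}
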