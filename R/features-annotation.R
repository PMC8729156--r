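# Binary annotation feature builders: gene-set membership matrices and
# ancestor-propagated ontology-term matrices.

#' Gene-set membership matrix
#'
#' One binary column per gene set; a cell is 1 iff the gene belongs to the
#' set. Genes with no membership are kept as all-zero rows — dropping them is
#' the caller's choice.
#'
#' @param gene_sets Named list of character vectors (set id -> member genes),
#'   e.g. from [read_gene_sets()].
#' @param genes Labels tibble (or any data frame with a `gene_id` column)
#'   defining the instance rows.
#' @return A binary feature tibble (`gene_id` + one column per set).
#' @examples
#' genes <- tibble::tibble(gene_id = c("g1", "g2"), label = c("DR", "NotDR"))
#' membership_matrix(list(P1 = "g1"), genes)
#' @export
membership_matrix <- function(gene_sets, genes) {
  if (!is.data.frame(genes) || !"gene_id" %in% names(genes) || nrow(genes) == 0L) {
    abort("`genes` must be a nonempty data frame with a `gene_id` column.")
  }
  ids <- genes$gene_id
  m <- matrix(0, nrow = length(ids), ncol = length(gene_sets),
              dimnames = list(ids, names(gene_sets)))
  for (s in names(gene_sets)) {
    m[ids %in% gene_sets[[s]], s] <- 1
  }
  fm_tibble(m)
}

# Ancestor sets for every term of a DAG, root included, self excluded.
dag_ancestors <- function(dag) {
  g <- igraph::graph_from_data_frame(dag$edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = dag$terms))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- which(comp$membership == which(comp$csize > 1)[1])
    nodes <- igraph::V(g)$name[cyc]
    e <- dag$edges[dag$edges$child %in% nodes & dag$edges$parent %in% nodes, ][1, ]
    abort(sprintf("Annotation graph has a cycle (e.g. edge %s -> %s).",
                  e$child, e$parent))
  }
  anc <- igraph::ego(g, order = igraph::vcount(g), mode = "out")
  setNames(lapply(seq_along(anc), function(i) {
    setdiff(igraph::V(g)$name[anc[[i]]], igraph::V(g)$name[i])
  }), igraph::V(g)$name)
}

#' Propagate annotations up an ontology DAG (true-path rule)
#'
#' Closes the direct gene-to-term annotations under the ancestor relation: a
#' gene annotated to a term becomes annotated to every ancestor of that term,
#' up to and including the root. Propagating an already-closed DAG changes
#' nothing (idempotence).
#'
#' @param dag A `dr_dag` (acyclic; a cycle raises an error naming one edge on
#'   the cycle).
#' @return The `dr_dag` with `annotations` replaced by their ancestor closure.
#' @export
propagate_annotations <- function(dag) {
  anc <- dag_ancestors(dag)
  if (nrow(dag$annotations) == 0L) return(dag)
  missing_terms <- setdiff(dag$annotations$term_id, dag$terms)
  if (length(missing_terms)) {
    abort(sprintf("Annotated terms absent from the DAG: %s",
                  paste(head(missing_terms, 3), collapse = ", ")))
  }
  closed <- dag$annotations |>
    mutate(term_id = purrr::map(.data$term_id, function(t) c(t, anc[[t]]))) |>
    tidyr::unnest("term_id") |>
    dplyr::distinct()
  dag$annotations <- closed
  dag
}

#' Binary ontology-term matrix from a closed DAG
#'
#' One binary column per term present in the ancestor-closed annotation set.
#' Genes with zero annotations are dropped from the matrix (they carry no
#' ontology information), mirroring the removal of unannotated genes from the
#' ontology dataset.
#'
#' @param dag A `dr_dag`; closed with [propagate_annotations()] first if
#'   `propagate = TRUE` (default).
#' @param genes Labels tibble defining candidate instance rows.
#' @param propagate Apply the ancestor closure before building the matrix?
#' @return A binary feature tibble over the annotated genes only.
#' @export
go_matrix <- function(dag, genes, propagate = TRUE) {
  if (propagate) dag <- propagate_annotations(dag)
  ann <- dag$annotations |> filter(.data$gene_id %in% genes$gene_id)
  keep_genes <- intersect(genes$gene_id, unique(ann$gene_id))
  terms <- sort(unique(ann$term_id))
  m <- matrix(0, nrow = length(keep_genes), ncol = length(terms),
              dimnames = list(keep_genes, terms))
  m[cbind(match(ann$gene_id, keep_genes), match(ann$term_id, terms))] <- 1
  fm_tibble(m)
}
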