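# Plain-text IO. TSV is the canonical tabular dialect with "NA" for missing;
# gene sets travel as GMT; graphs as two-column edge lists; DAGs as
# child -> parent edge TSVs. Writers sort ids so outputs diff cleanly.

#' Read / write a gene-label table
#'
#' The file is a TSV with columns `gene_id` and `label` (`DR` / `NotDR`).
#'
#' @param path File path.
#' @return `read_labels()`: a tibble with columns `gene_id`, `label`.
#' @export
read_labels <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  check_labels(x)
  as_tibble(x)
}

#' @rdname read_labels
#' @param labels Labels tibble.
#' @export
write_labels <- function(labels, path) {
  check_labels(labels)
  readr::write_tsv(dplyr::arrange(as_tibble(labels), .data$gene_id), path)
  invisible(path)
}

#' Read / write a feature matrix
#'
#' TSV with a `gene_id` column followed by one numeric column per feature;
#' missing cells are `NA`. On reading, a column's kind is inferred as binary
#' iff its non-missing values are a subset of \{0, 1\} (see [feature_kinds()]).
#'
#' @param path File path.
#' @return `read_matrix()`: a feature tibble.
#' @export
read_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(x$gene_id)) abort("Duplicate gene ids in matrix file.")
  if (anyDuplicated(names(x))) abort("Duplicate feature ids in matrix file.")
  as_tibble(x)
}

#' @rdname read_matrix
#' @param x Feature tibble.
#' @export
write_matrix <- function(x, path) {
  stopifnot("gene_id" %in% names(x))
  x <- dplyr::arrange(as_tibble(x), .data$gene_id)
  x <- x[, c("gene_id", sort(setdiff(names(x), "gene_id")))]
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path File path.
#' @return `read_gene_sets()`: a named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      abort(sprintf("Malformed GMT line %d: need at least id and description.", i))
    }
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  ids <- sort(names(sets))
  lines <- vapply(ids, function(id) {
    paste(c(id, id, sort(sets[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a graph as a two-column edge list
#'
#' TSV with columns `from` and `to`. Undirected edges are canonicalized on
#' reading (sorted endpoints), so `a b` and `b a` collapse to a single edge;
#' loops and repeated edges are removed for undirected graphs.
#'
#' @param path File path.
#' @param directed Read as a directed graph?
#' @return `read_edge_list()`: an `igraph`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("from", "to") %in% names(x))) {
    abort("Edge list must have columns `from` and `to`.")
  }
  g <- igraph::graph_from_data_frame(x, directed = directed)
  if (!directed) g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g
}

#' @rdname read_edge_list
#' @param graph An `igraph`.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")[, c("from", "to")]
  if (!igraph::is_directed(graph)) {
    swap <- el$from > el$to
    tmp <- el$from[swap]; el$from[swap] <- el$to[swap]; el$to[swap] <- tmp
    el <- unique(el)
  }
  el <- el[order(el$from, el$to), ]
  readr::write_tsv(as_tibble(el), path)
  invisible(path)
}

#' Read / write direct gene-to-term annotations
#'
#' TSV with columns `gene_id` and `term_id`.
#'
#' @param path File path.
#' @return `read_annotations()`: a tibble `gene_id`, `term_id`.
#' @export
read_annotations <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(x))) {
    abort("Annotation file must have columns `gene_id` and `term_id`.")
  }
  dplyr::distinct(as_tibble(x))
}

#' @rdname read_annotations
#' @param annotations Tibble with `gene_id`, `term_id`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(dplyr::arrange(as_tibble(annotations), .data$gene_id, .data$term_id),
                   path)
  invisible(path)
}

#' Write a DAG's edges as a child -> parent TSV
#' @param dag A `dr_dag`.
#' @param path File path.
#' @export
write_dag_edges <- function(dag, path) {
  readr::write_tsv(dplyr::arrange(as_tibble(dag$edges), .data$child, .data$parent), path)
  invisible(path)
}

#' Read a DAG from a child -> parent edge TSV plus annotations
#' @param edges_path Edge TSV with columns `child`, `parent`.
#' @param annotations Tibble of direct annotations (`gene_id`, `term_id`).
#' @return A `dr_dag`.
#' @export
read_dag <- function(edges_path, annotations = tibble(gene_id = character(),
                                                      term_id = character())) {
  e <- readr::read_tsv(edges_path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("child", "parent") %in% names(e))) {
    abort("DAG edge file must have columns `child` and `parent`.")
  }
  terms <- unique(c(e$child, e$parent))
  roots <- setdiff(e$parent, e$child)
  if (length(roots) != 1L) {
    abort(sprintf("DAG must have exactly one root; found %d.", length(roots)))
  }
  structure(list(terms = terms, edges = as_tibble(e), root = roots,
                 annotations = dplyr::distinct(as_tibble(annotations))),
            class = "dr_dag")
}
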