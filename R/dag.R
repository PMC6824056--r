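#' Disease DAG for semantic similarity
#'
#' A MeSH-style directed acyclic graph describing one disease: the disease
#' term itself plus all its ancestor terms, with directed child-to-parent
#' edges. Each ancestor contributes decay-weighted semantic credit to the
#' disease; two diseases are semantically similar in proportion to the
#' credit carried by their shared terms.
#'
#' @param disease_id term label of the disease the DAG describes.
#' @param edges two-column data frame (child, parent) of directed edges;
#'   may be empty for a single-node DAG.
#' @param decay semantic contribution decay factor in (0, 1); each step away
#'   from the disease multiplies the credit by this factor. Default 0.5.
#' @return object of class `disease_dag` with elements `disease_id`,
#'   `nodes`, `edges` (character matrix, child/parent columns), `decay`.
#'   Rejects cyclic graphs and nodes not reachable from the disease along
#'   child-to-parent edges (i.e. nodes that are not ancestors of the
#'   disease).
#' @export
disease_dag <- function(disease_id, edges = NULL, decay = 0.5) {
  stopifnot(is.character(disease_id), length(disease_id) == 1L)
  if (!(is.numeric(decay) && length(decay) == 1L && decay > 0 && decay < 1)) {
    stop("decay must be a scalar in (0, 1)")
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2, dimnames = list(NULL, c("child", "parent")))
    return(structure(
      list(disease_id = disease_id, nodes = disease_id, edges = em, decay = decay),
      class = "disease_dag"
    ))
  }
  edges <- as.data.frame(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns: child, parent")
  em <- cbind(child = as.character(edges[[1]]), parent = as.character(edges[[2]]))
  if (any(em[, 1] == em[, 2])) stop("self-loop edges are not allowed")
  if (anyDuplicated(paste(em[, 1], em[, 2], sep = "\r"))) {
    stop("duplicate edges are not allowed")
  }
  nodes <- union(disease_id, unique(c(em)))
  g <- igraph::graph_from_edgelist(em, directed = TRUE)
  g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
  if (!igraph::is_dag(g)) stop("cycle detected: the term graph must be acyclic")
  # every node must be an ancestor of the disease (or the disease itself):
  # reachable from disease_id along child->parent edges
  reach <- igraph::subcomponent(g, disease_id, mode = "out")$name
  bad <- setdiff(nodes, reach)
  if (length(bad) > 0) {
    stop("nodes not ancestors of '", disease_id, "': ", paste(bad, collapse = ", "))
  }
  structure(
    list(disease_id = disease_id, nodes = nodes, edges = em, decay = decay),
    class = "disease_dag"
  )
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf(
    "disease_dag '%s': %d terms, %d edges, decay %.3g\n",
    x$disease_id, length(x$nodes), nrow(x$edges), x$decay
  ))
  invisible(x)
}

#' Semantic value of a disease from its DAG
#'
#' The disease term contributes 1 to itself; every other term contributes
#' `decay` times the largest contribution among its children inside the DAG,
#' so credit decays with distance from the disease along the best path. The
#' semantic value of the disease is the sum of all term contributions.
#'
#' @param dag a [disease_dag()].
#' @return list with `contrib` (named numeric vector of per-term
#'   contributions) and `sv` (their sum, the disease's semantic value).
#' @examples
#' d <- disease_dag("D", data.frame(child = c("D", "mid"),
#'                                  parent = c("mid", "root")))
#' semantic_value(d)$sv  # 1 + 0.5 + 0.25 = 1.75
#' @export
semantic_value <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  contrib <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  contrib[dag$disease_id] <- 1
  if (nrow(dag$edges) > 0) {
    g <- igraph::graph_from_edgelist(dag$edges, directed = TRUE)
    g <- g + igraph::vertices(setdiff(dag$nodes, igraph::V(g)$name))
    # child->parent edges: topological order puts children before parents,
    # so each node's children are resolved when it is visited
    ord <- igraph::topo_sort(g, mode = "out")$name
    for (v in ord) {
      if (v == dag$disease_id) next
      ch <- dag$edges[dag$edges[, "parent"] == v, "child"]
      contrib[v] <- dag$decay * max(contrib[ch])
    }
  }
  if (anyNA(contrib)) stop("internal error: unresolved term contribution")
  list(contrib = contrib, sv = sum(contrib))
}

#' Semantic similarity between two diseases
#'
#' Shared-term credit normalized by total credit: the contributions of terms
#' present in both DAGs (matched by label), summed from both sides, divided
#' by the sum of the two semantic values. Identical DAGs give 1, DAGs with
#' disjoint term sets give 0.
#'
#' @param dag_i,dag_j [disease_dag()] objects; must use the same decay.
#' @param sv_i,sv_j optional precomputed [semantic_value()] results, to
#'   avoid recomputation when scoring many pairs.
#' @return scalar in `[0, 1]`.
#' @export
semantic_similarity <- function(dag_i, dag_j, sv_i = NULL, sv_j = NULL) {
  stopifnot(inherits(dag_i, "disease_dag"), inherits(dag_j, "disease_dag"))
  if (dag_i$decay != dag_j$decay) stop("DAGs must share the same decay factor")
  if (is.null(sv_i)) sv_i <- semantic_value(dag_i)
  if (is.null(sv_j)) sv_j <- semantic_value(dag_j)
  shared <- intersect(names(sv_i$contrib), names(sv_j$contrib))
  if (length(shared) == 0) return(0)
  sum(sv_i$contrib[shared] + sv_j$contrib[shared]) / (sv_i$sv + sv_j$sv)
}
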