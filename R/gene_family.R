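#' Gene-family network for one microbe pair
#'
#' Undirected network over gene families drawn from two genomes A and B.
#' Each family is tagged by genome membership: present only in A, only in
#' B, or in both. Edges link functionally associated families (e.g. gene
#' neighbor relationships); the fraction of edges crossing the A/B boundary
#' among edges between genome-exclusive families measures how intertwined
#' the two genomes' functions are.
#'
#' @param families named character vector: names are family labels, values
#'   their membership, one of `"A"`, `"B"`, `"both"`.
#' @param edges two-column data frame (from, to) of undirected edges between
#'   family labels; no self-loops, no duplicates (order-insensitive).
#' @return object of class `gene_family_network`.
#' @export
gene_family_network <- function(families, edges) {
  stopifnot(is.character(families), !is.null(names(families)))
  if (anyDuplicated(names(families))) stop("duplicate family labels")
  if (!all(families %in% c("A", "B", "both"))) {
    stop('family memberships must be "A", "B" or "both"')
  }
  edges <- as.data.frame(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  u <- as.character(edges[[1]]); v <- as.character(edges[[2]])
  if (!all(c(u, v) %in% names(families))) stop("edge endpoint not in families")
  if (any(u == v)) stop("self-loop edges are not allowed")
  key <- ifelse(u < v, paste(u, v, sep = "\r"), paste(v, u, sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate undirected edges are not allowed")
  structure(
    list(families = families, edges = cbind(from = u, to = v)),
    class = "gene_family_network"
  )
}

#' Cross-boundary functional similarity of a microbe pair
#'
#' The fraction of edges joining a genome-A-only family to a genome-B-only
#' family among all edges whose two endpoints are both genome-exclusive
#' (A-A, B-B or A-B). Edges touching a family present in both genomes are
#' ignored on both sides of the ratio. When no qualifying edge exists the
#' similarity is defined as 0 (with a warning) so that integrated microbe
#' similarity stays defined everywhere.
#'
#' @param gfn a [gene_family_network()].
#' @return scalar in `[0, 1]`.
#' @export
functional_similarity <- function(gfn) {
  stopifnot(inherits(gfn, "gene_family_network"))
  mu <- gfn$families[gfn$edges[, "from"]]
  mv <- gfn$families[gfn$edges[, "to"]]
  qualifying <- mu != "both" & mv != "both"
  n_qual <- sum(qualifying)
  if (n_qual == 0) {
    warning("no edges between genome-exclusive families; functional similarity set to 0")
    return(0)
  }
  sum(qualifying & mu != mv) / n_qual
}
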