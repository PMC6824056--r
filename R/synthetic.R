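#' Specification of a planted-block synthetic dataset
#'
#' Describes a synthetic study in which diseases and microbes fall into
#' latent blocks: associations are dense inside a block and sparse across
#' blocks, diseases of a block share DAG ancestors (so their semantic
#' similarity is high), and microbe pairs of a block have gene-family
#' networks with a high cross-boundary edge fraction (high functional
#' similarity). This is the minimal generative structure matching the
#' guilt-by-association assumption the scoring model relies on; it is a
#' stand-in for curated association databases, not a model of them.
#'
#' @param n_d,n_m numbers of diseases and microbes (defaults 20 and 30).
#' @param blocks number of latent blocks (default 2).
#' @param within_density,cross_density association probabilities inside and
#'   across blocks (defaults 0.4 and 0.02); must satisfy
#'   `0 <= cross < within <= 1`.
#' @param dag_depth depth of each disease DAG including the disease term
#'   (default 3; depth 1 means single-node DAGs, hence no semantic
#'   information).
#' @param dag_branching number of level-1 block ancestors each disease
#'   attaches to (default 2).
#' @param fs_within,fs_cross target cross-boundary edge fractions of the
#'   gene-family networks for same-block and cross-block microbe pairs
#'   (defaults 0.7 and 0.1).
#' @param gfn_edges edges per gene-family network (default 200).
#' @param seed integer seed fixing all randomness (default 1).
#' @return list of class `planted_spec`.
#' @export
planted_spec <- function(n_d = 20L, n_m = 30L, blocks = 2L,
                         within_density = 0.4, cross_density = 0.02,
                         dag_depth = 3L, dag_branching = 2L,
                         fs_within = 0.7, fs_cross = 0.1,
                         gfn_edges = 200L, seed = 1L) {
  stopifnot(
    n_d >= 1, n_m >= 1, blocks >= 1,
    within_density >= 0, within_density <= 1,
    cross_density >= 0, cross_density <= 1,
    cross_density < within_density || within_density == cross_density,
    dag_depth >= 1, dag_branching >= 1,
    fs_cross >= 0, fs_cross <= fs_within, fs_within <= 1,
    gfn_edges >= 1
  )
  structure(
    list(n_d = as.integer(n_d), n_m = as.integer(n_m),
         blocks = as.integer(blocks),
         within_density = within_density, cross_density = cross_density,
         dag_depth = as.integer(dag_depth),
         dag_branching = as.integer(dag_branching),
         fs_within = fs_within, fs_cross = fs_cross,
         gfn_edges = as.integer(gfn_edges), seed = as.integer(seed)),
    class = "planted_spec"
  )
}

# Round-robin block assignment used for both node classes.
block_of <- function(n, blocks) ((seq_len(n) - 1L) %% blocks) + 1L

#' Generate a planted-block association matrix
#'
#' Entry (i, j) is 1 with probability `within_density` when disease i and
#' microbe j share a block and `cross_density` otherwise; blocks are
#' assigned round-robin. Deterministic given the spec's seed.
#'
#' @param spec a [planted_spec()].
#' @return an [association_matrix()] of size `n_d` x `n_m`.
#' @export
generate_bipartite <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  bd <- block_of(spec$n_d, spec$blocks)
  bm <- block_of(spec$n_m, spec$blocks)
  p <- ifelse(outer(bd, bm, "=="), spec$within_density, spec$cross_density)
  set.seed(spec$seed)
  entries <- matrix(stats::rbinom(length(p), 1, p), spec$n_d, spec$n_m)
  association_matrix(entries,
                     disease_ids = paste0("d", seq_len(spec$n_d)),
                     microbe_ids = paste0("m", seq_len(spec$n_m)))
}

#' Generate a forest of block-sharing disease DAGs
#'
#' Each disease's DAG is the disease term plus a chain of ancestors shared
#' by its block (`dag_branching` parallel level-1 ancestors feeding a
#' common chain) topped by one global root, so same-block diseases share
#' most of their ancestry and cross-block diseases share only the root.
#' With `dag_depth = 1` every DAG is a single node and all off-diagonal
#' semantic similarities are 0.
#'
#' @param spec a [planted_spec()].
#' @param decay semantic decay factor passed to [disease_dag()].
#' @return named list of [disease_dag()] objects, one per disease.
#' @export
generate_dag_forest <- function(spec, decay = 0.5) {
  stopifnot(inherits(spec, "planted_spec"))
  bd <- block_of(spec$n_d, spec$blocks)
  dags <- vector("list", spec$n_d)
  names(dags) <- paste0("d", seq_len(spec$n_d))
  for (i in seq_len(spec$n_d)) {
    id <- names(dags)[i]
    if (spec$dag_depth == 1L) {
      dags[[i]] <- disease_dag(id, decay = decay)
      next
    }
    b <- bd[i]
    lvl1 <- paste0("blk", b, "_a1_", seq_len(spec$dag_branching))
    edges <- data.frame(child = id, parent = lvl1)
    prev <- lvl1
    if (spec$dag_depth > 2L) {
      for (lev in 2:(spec$dag_depth - 1L)) {
        node <- paste0("blk", b, "_a", lev)
        edges <- rbind(edges, data.frame(child = prev, parent = node))
        prev <- node
      }
    }
    edges <- rbind(edges, data.frame(child = prev, parent = "root"))
    dags[[i]] <- disease_dag(id, edges, decay = decay)
  }
  dags
}

#' Generate gene-family networks for every microbe pair
#'
#' For each unordered microbe pair a labeled gene-family network of
#' `gfn_edges` edges between genome-exclusive families is drawn: each edge
#' crosses the A/B boundary with probability `fs_within` (same block) or
#' `fs_cross` (different blocks), otherwise it stays within a randomly
#' chosen genome. The realized cross-boundary fraction is therefore
#' binomially concentrated around the block-level target.
#'
#' @param spec a [planted_spec()].
#' @return named list (keys `"mi|mj"`, i < j) of [gene_family_network()]
#'   objects.
#' @export
generate_gene_family_networks <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  bm <- block_of(spec$n_m, spec$blocks)
  set.seed(spec$seed + 1L)
  out <- list()
  ne <- spec$gfn_edges
  # family pool per genome sized so each edge class can host `ne` distinct
  # edges: within-genome pool choose(n_fam, 2), cross pool n_fam^2
  n_fam <- max(8L, ceiling(sqrt(2 * ne)) + 3L)
  fam_a <- paste0("fa", seq_len(n_fam)); fam_b <- paste0("fb", seq_len(n_fam))
  families <- stats::setNames(
    c(rep("A", n_fam), rep("B", n_fam), "both"),
    c(fam_a, fam_b, "f_shared")
  )
  within_pairs <- t(utils::combn(n_fam, 2L))
  cross_pairs <- as.matrix(expand.grid(a = seq_len(n_fam), b = seq_len(n_fam)))
  for (i in seq_len(spec$n_m - 1L)) {
    for (j in (i + 1L):spec$n_m) {
      p <- if (bm[i] == bm[j]) spec$fs_within else spec$fs_cross
      n_cross <- stats::rbinom(1, ne, p)
      n_within <- ne - n_cross
      n_wa <- stats::rbinom(1, n_within, 0.5)
      n_wb <- n_within - n_wa
      cr <- cross_pairs[sample.int(nrow(cross_pairs), n_cross), , drop = FALSE]
      wa <- within_pairs[sample.int(nrow(within_pairs), n_wa), , drop = FALSE]
      wb <- within_pairs[sample.int(nrow(within_pairs), n_wb), , drop = FALSE]
      edges <- data.frame(
        from = c(fam_a[cr[, 1]], fam_a[wa[, 1]], fam_b[wb[, 1]]),
        to = c(fam_b[cr[, 2]], fam_a[wa[, 2]], fam_b[wb[, 2]])
      )
      out[[paste0("m", i, "|m", j)]] <- gene_family_network(families, edges)
    }
  }
  out
}

#' Functional-similarity matrix of a planted spec
#'
#' Applies [functional_similarity()] to each generated gene-family network
#' and assembles the symmetric microbe similarity matrix, diagonal set
#' to 1 by convention.
#'
#' @param spec a [planted_spec()].
#' @param gfns optional pre-generated network list from
#'   [generate_gene_family_networks()].
#' @return `n_m` x `n_m` similarity matrix.
#' @export
generate_functional_similarity <- function(spec, gfns = NULL) {
  stopifnot(inherits(spec, "planted_spec"))
  if (is.null(gfns)) gfns <- generate_gene_family_networks(spec)
  FS <- diag(spec$n_m)
  ids <- paste0("m", seq_len(spec$n_m))
  dimnames(FS) <- list(ids, ids)
  for (key in names(gfns)) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    s <- functional_similarity(gfns[[key]])
    FS[pair[1], pair[2]] <- FS[pair[2], pair[1]] <- s
  }
  FS
}

#' Assemble a complete planted synthetic dataset
#'
#' Convenience wrapper running all three generators and bundling the
#' results into an [mda_dataset()].
#'
#' @param spec a [planted_spec()].
#' @param decay DAG semantic decay factor.
#' @return an `mda_dataset`.
#' @export
planted_dataset <- function(spec = planted_spec(), decay = 0.5) {
  A <- generate_bipartite(spec)
  dags <- generate_dag_forest(spec, decay = decay)
  FS <- generate_functional_similarity(spec)
  mda_dataset(A, dags = dags, FS = FS)
}

#' Entry-permuted null dataset
#'
#' Re-scatters the known associations uniformly over the matrix cells
#' (preserving their count) so that any alignment between the association
#' pattern and the block structure of the prior similarities is destroyed.
#' This is the label-permutation null against which planted-signal
#' detection is measured.
#'
#' @param dataset an [mda_dataset()].
#' @param seed RNG seed.
#' @return an `mda_dataset` with the same DAGs and functional similarity
#'   but permuted associations.
#' @export
permute_associations <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "mda_dataset"))
  n_known <- sum(dataset$A)
  A <- dataset$A
  A[] <- 0
  set.seed(seed)
  A[sample(length(A), n_known)] <- 1
  mda_dataset(A, dags = dataset$dags,
              FS = if (all(dataset$FS == diag(ncol(A)))) NULL else dataset$FS)
}
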