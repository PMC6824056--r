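#' Construct a binary disease-microbe association matrix
#'
#' The adjacency matrix `A` of the known disease-microbe bipartite network.
#' Rows are diseases, columns are microbes; `A[i, j] == 1` records an
#' experimentally supported association. Row `i` is the interaction profile
#' of disease `i` and column `j` the interaction profile of microbe `j`.
#'
#' @param entries numeric matrix of 0/1 entries.
#' @param disease_ids,microbe_ids ordered labels; default to the dimnames of
#'   `entries`, or `d1..`/`m1..` when absent.
#' @return a base matrix with class attribute left untouched; dimnames carry
#'   the labels. Invalid input errors.
#' @export
association_matrix <- function(entries,
                               disease_ids = rownames(entries),
                               microbe_ids = colnames(entries)) {
  entries <- as.matrix(entries)
  if (is.null(disease_ids)) disease_ids <- paste0("d", seq_len(nrow(entries)))
  if (is.null(microbe_ids)) microbe_ids <- paste0("m", seq_len(ncol(entries)))
  if (length(disease_ids) != nrow(entries) || length(microbe_ids) != ncol(entries)) {
    stop("label lengths do not match matrix dimensions")
  }
  if (anyDuplicated(disease_ids) || anyDuplicated(microbe_ids)) {
    stop("disease and microbe labels must be unique")
  }
  storage.mode(entries) <- "double"
  if (anyNA(entries) || !all(entries %in% c(0, 1))) {
    stop("association matrix entries must be exactly 0 or 1")
  }
  dimnames(entries) <- list(disease_ids, microbe_ids)
  entries
}

#' @rdname association_matrix
#' @param A object to validate.
#' @export
validate_association_matrix <- function(A) {
  stopifnot(is.matrix(A), is.numeric(A))
  if (anyNA(A) || !all(A %in% c(0, 1))) {
    stop("association matrix entries must be exactly 0 or 1")
  }
  invisible(A)
}

#' Bundle the inputs of one prediction problem
#'
#' Holds the association matrix together with the optional prior-knowledge
#' inputs: per-disease DAGs (for semantic similarity) and a precomputed
#' microbe functional-similarity matrix. The DAG-derived semantic similarity
#' and its availability mask do not depend on the association matrix, so they
#' are computed once here and cached; only the interaction-profile kernels
#' are recomputed per cross-validation round.
#'
#' @param A association matrix from [association_matrix()].
#' @param dags optional named list of [disease_dag()] objects; names must be
#'   a subset of the disease labels of `A`.
#' @param FS optional square microbe functional-similarity matrix with
#'   dimnames equal to the microbe labels of `A`; entries in `[0, 1]`. When
#'   absent, FS defaults to the identity (no functional information, so the
#'   integrated microbe similarity for distinct pairs falls back toward the
#'   kernel term).
#' @return object of class `mda_dataset`: list with elements `A`, `dags`,
#'   `FS`, `SS` (cached semantic similarity over all diseases, 0 where
#'   undefined), and `semantic_mask` (logical matrix: both endpoints have a
#'   DAG).
#' @export
mda_dataset <- function(A, dags = NULL, FS = NULL) {
  validate_association_matrix(A)
  disease_ids <- rownames(A)
  microbe_ids <- colnames(A)
  if (!is.null(dags)) {
    if (is.null(names(dags)) || !all(names(dags) %in% disease_ids)) {
      stop("names of `dags` must be disease labels of `A`")
    }
    for (g in dags) stopifnot(inherits(g, "disease_dag"))
  }
  if (is.null(FS)) {
    FS <- diag(ncol(A))
    dimnames(FS) <- list(microbe_ids, microbe_ids)
  } else {
    FS <- as.matrix(FS)
    if (!identical(rownames(FS), microbe_ids) || !identical(colnames(FS), microbe_ids)) {
      stop("FS dimnames must equal the microbe labels of `A`")
    }
    check_similarity_matrix(FS)
  }
  ss <- semantic_similarity_matrix(dags, disease_ids)
  structure(
    list(A = A, dags = dags, FS = FS, SS = ss$SS, semantic_mask = ss$mask),
    class = "mda_dataset"
  )
}

#' @export
print.mda_dataset <- function(x, ...) {
  cat(sprintf(
    "mda_dataset: %d diseases x %d microbes, %d known associations\n",
    nrow(x$A), ncol(x$A), sum(x$A)
  ))
  cat(sprintf(
    "  DAGs for %d diseases; functional similarity %s\n",
    if (is.null(x$dags)) 0L else length(x$dags),
    if (all(x$FS == diag(ncol(x$A)))) "absent (identity)" else "supplied"
  ))
  invisible(x)
}

# Semantic similarity over all diseases plus the pair-availability mask used
# by the integrated disease similarity: TRUE iff both endpoints have a DAG.
semantic_similarity_matrix <- function(dags, disease_ids) {
  n <- length(disease_ids)
  SS <- diag(n)
  mask <- matrix(FALSE, n, n)
  dimnames(SS) <- dimnames(mask) <- list(disease_ids, disease_ids)
  if (!is.null(dags) && length(dags) > 0) {
    covered <- intersect(disease_ids, names(dags))
    sv <- lapply(dags[covered], semantic_value)
    mask[covered, covered] <- TRUE
    for (ia in seq_along(covered)) {
      for (ib in seq_len(ia)) {
        a <- covered[ia]; b <- covered[ib]
        s <- semantic_similarity(dags[[a]], dags[[b]],
                                 sv_i = sv[[a]], sv_j = sv[[b]])
        SS[a, b] <- SS[b, a] <- s
      }
    }
  }
  list(SS = SS, mask = mask)
}
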