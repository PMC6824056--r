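# Shared checks for square similarity matrices: symmetric within 1e-10,
# nonnegative; optionally unit diagonal.
check_similarity_matrix <- function(S, unit_diag = FALSE, tol = 1e-10) {
  stopifnot(is.matrix(S), is.numeric(S), nrow(S) == ncol(S))
  if (anyNA(S) || any(!is.finite(S))) stop("similarity matrix has non-finite entries")
  if (any(S < 0)) stop("similarity matrix has negative entries")
  if (max(abs(S - t(S))) > tol) stop("similarity matrix is not symmetric within tolerance")
  if (unit_diag && any(abs(diag(S) - 1) > tol)) stop("similarity diagonal must be 1")
  invisible(S)
}

# Enforce exact floating-point symmetry after construction.
symmetrize <- function(S) (S + t(S)) / 2

#' Gaussian interaction-profile kernel similarity
#'
#' Similarity between two diseases (or two microbes) computed from their
#' binary interaction profiles: `exp(-lambda * ||IP(i) - IP(j)||^2)` with a
#' data-adaptive bandwidth `lambda = bandwidth_mult / mean(||IP||^2)`, the
#' mean taken over all profiles on the chosen axis. Disease profiles are the
#' rows of the association matrix, microbe profiles its columns.
#'
#' @param A association matrix (see [association_matrix()]).
#' @param axis `"disease"` (kernel over rows) or `"microbe"` (over columns).
#' @param bandwidth_mult positive bandwidth multiplier (default 1).
#' @return symmetric similarity matrix with unit diagonal, labelled by the
#'   ids on the chosen axis. An all-zero association matrix leaves the
#'   bandwidth undefined and is rejected.
#' @examples
#' A <- association_matrix(diag(2))
#' gip_kernel(A, "disease")[1, 2]  # exp(-2)
#' @export
gip_kernel <- function(A, axis = c("disease", "microbe"), bandwidth_mult = 1) {
  axis <- match.arg(axis)
  validate_association_matrix(A)
  stopifnot(is.numeric(bandwidth_mult), length(bandwidth_mult) == 1L, bandwidth_mult > 0)
  P <- if (axis == "disease") A else t(A)
  sq <- rowSums(P^2)
  if (mean(sq) == 0) {
    stop("all interaction profiles are zero: kernel bandwidth is undefined")
  }
  lambda <- bandwidth_mult / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0 # numerical guard
  K <- exp(-lambda * d2)
  diag(K) <- 1
  K <- symmetrize(K)
  dimnames(K) <- list(rownames(P), rownames(P))
  check_similarity_matrix(K, unit_diag = TRUE)
  K
}

#' Integrated disease similarity
#'
#' Convex blend of semantic and kernel similarity where semantic similarity
#' is available, plain kernel similarity elsewhere. Availability is
#' pair-level: a pair blends iff both endpoint diseases have a DAG,
#' regardless of the magnitude of their semantic similarity.
#'
#' @param SS semantic similarity matrix (0 where undefined).
#' @param GD Gaussian kernel disease similarity.
#' @param alpha blend weight on the semantic term, in `[0, 1]`; default 0.6.
#' @param semantic_defined logical matrix marking pairs where both diseases
#'   have a DAG; must be symmetric. Default: everywhere `TRUE`.
#' @return symmetric integrated disease similarity matrix DS.
#' @export
integrate_disease_similarity <- function(SS, GD, alpha = 0.6,
                                         semantic_defined = NULL) {
  check_similarity_matrix(SS)
  check_similarity_matrix(GD)
  if (!all(dim(SS) == dim(GD))) stop("SS and GD dimensions differ")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  if (is.null(semantic_defined)) {
    semantic_defined <- matrix(TRUE, nrow(SS), ncol(SS))
  }
  stopifnot(is.logical(semantic_defined), all(dim(semantic_defined) == dim(SS)))
  if (!identical(semantic_defined, t(semantic_defined))) {
    stop("semantic_defined mask must be symmetric")
  }
  DS <- ifelse(semantic_defined, alpha * SS + (1 - alpha) * GD, GD)
  DS <- symmetrize(DS)
  dimnames(DS) <- dimnames(GD)
  DS
}

#' Integrated microbe similarity
#'
#' Elementwise convex combination `beta * FS + (1 - beta) * GM` of the
#' functional similarity and the Gaussian kernel microbe similarity.
#'
#' @param FS microbe functional similarity matrix.
#' @param GM Gaussian kernel microbe similarity.
#' @param beta blend weight on the functional term, in `[0, 1]`; default 0.7.
#' @return symmetric integrated microbe similarity matrix MS.
#' @export
integrate_microbe_similarity <- function(FS, GM, beta = 0.7) {
  check_similarity_matrix(FS)
  check_similarity_matrix(GM)
  if (!all(dim(FS) == dim(GM))) stop("FS and GM dimensions differ")
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1)
  MS <- symmetrize(beta * FS + (1 - beta) * GM)
  dimnames(MS) <- dimnames(GM)
  MS
}

#' Symmetric normalization of a similarity matrix
#'
#' Divides each entry by the square root of the product of its row and
#' column sums, the normalization under which the meta-graph fixed-point
#' iteration is guaranteed to converge (spectral radius at most 1). A node
#' with zero row sum (possible after cross-validation masking isolates it)
#' keeps a zero row and column rather than producing NaN.
#'
#' @param S square nonnegative matrix.
#' @return normalized matrix of the same shape; symmetric when `S` is.
#' @export
symmetric_normalize <- function(S) {
  stopifnot(is.matrix(S), is.numeric(S), nrow(S) == ncol(S))
  if (any(S < 0)) stop("symmetric_normalize requires nonnegative entries")
  rs <- rowSums(S)
  cs <- colSums(S)
  if (any(rs == 0)) {
    warning("node(s) with zero similarity row sum: normalized rows set to 0")
  }
  denom <- sqrt(outer(rs, cs))
  out <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  ok <- denom > 0
  out[ok] <- S[ok] / denom[ok]
  out
}

#' Compute integrated, normalized similarities for one training matrix
#'
#' The per-round similarity rebuild used by prediction and every
#' cross-validation scheme: interaction-profile kernels are recomputed from
#' the training association matrix, blended with the dataset's cached
#' semantic and functional similarities, and symmetrically normalized for
#' propagation. A training matrix with no remaining associations carries no
#' profile information, so its kernels degrade to the identity and the
#' blends rest on the prior similarities alone.
#'
#' @param dataset an [mda_dataset()].
#' @param A_train training association matrix (defaults to `dataset$A`);
#'   same shape and labels as `dataset$A`, typically with held-out entries
#'   zeroed.
#' @param params a [wmg_params()] list supplying `alpha`, `beta` and the
#'   kernel bandwidth multipliers.
#' @return list with raw `DS`, `MS` and normalized `DSn`, `MSn`.
#' @export
wmg_similarities <- function(dataset, A_train = dataset$A, params = wmg_params()) {
  stopifnot(inherits(dataset, "mda_dataset"))
  validate_association_matrix(A_train)
  if (!all(dim(A_train) == dim(dataset$A))) stop("A_train shape mismatch")
  if (sum(A_train) == 0) {
    GD <- diag(nrow(A_train)); dimnames(GD) <- list(rownames(A_train), rownames(A_train))
    GM <- diag(ncol(A_train)); dimnames(GM) <- list(colnames(A_train), colnames(A_train))
  } else {
    GD <- gip_kernel(A_train, "disease", params$bandwidth_mult_d)
    GM <- gip_kernel(A_train, "microbe", params$bandwidth_mult_m)
  }
  DS <- integrate_disease_similarity(dataset$SS, GD, params$alpha, dataset$semantic_mask)
  MS <- integrate_microbe_similarity(dataset$FS, GM, params$beta)
  list(DS = DS, MS = MS, DSn = symmetric_normalize(DS), MSn = symmetric_normalize(MS))
}
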