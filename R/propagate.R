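#' Fixed-point meta-graph score propagation
#'
#' Iterates the weighted meta-graph update until the score matrix is
#' stable:
#' \deqn{P_{t+1} = \mu[\lambda_1 P_t + \lambda_2 (DS - I) P_t
#'   + \lambda_3 P_t (MS - I) + \lambda_4 (DS - I) P_t (MS - I)
#'   + \lambda_5 ((DS - I) P_t \odot (DS - I) P_t)^\gamma
#'   + \lambda_6 (P_t (MS - I) \odot P_t (MS - I))^\gamma] + (1 - \mu) A}
#' with the Hadamard product and the \eqn{\gamma} power taken elementwise.
#' `DS` and `MS` should be symmetrically normalized (see
#' [symmetric_normalize()]) so that the linear part is non-expansive.
#'
#' @param DS,MS normalized integrated similarity matrices.
#' @param A binary association matrix.
#' @param params a [wmg_params()].
#' @return object of class `prediction_matrix`: list with `scores`
#'   (disease x microbe, finite and nonnegative), `iterations`, `converged`,
#'   and `delta` (final max absolute change).
#' @export
propagate <- function(DS, MS, A, params = wmg_params()) {
  stopifnot(inherits(params, "wmg_params"))
  validate_association_matrix(A)
  stopifnot(nrow(DS) == nrow(A), ncol(DS) == nrow(A),
            nrow(MS) == ncol(A), ncol(MS) == ncol(A))
  mu <- params$mu; g <- params$gamma; lam <- params$bias
  DSo <- offdiag(DS)
  MSo <- offdiag(MS)
  P <- if (params$init == "global-max") {
    if (max(A) > 0) A / max(A) else A
  } else {
    rs <- rowSums(A)
    sweep(A, 1, ifelse(rs > 0, rs, 1), "/")
  }
  converged <- FALSE
  delta <- Inf
  iter <- 0L
  for (iter in seq_len(params$max_iter)) {
    dp <- DSo %*% P
    pm <- P %*% MSo
    if (any(dp < 0) || any(pm < 0)) {
      stop("negative intermediate term; DS/MS must be nonnegative")
    }
    bracket <- lam[1] * P + lam[2] * dp + lam[3] * pm +
      lam[4] * (DSo %*% P %*% MSo) +
      lam[5] * (dp * dp)^g +
      lam[6] * (pm * pm)^g
    P_next <- mu * bracket + (1 - mu) * A
    if (any(!is.finite(P_next))) {
      stop("non-finite scores at iteration ", iter, "; check input normalization")
    }
    delta <- max(abs(P_next - P))
    P <- P_next
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(P) <- dimnames(A)
  structure(
    list(scores = P, iterations = iter, converged = converged, delta = delta),
    class = "prediction_matrix"
  )
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf(
    "prediction_matrix: %d x %d scores; %d iterations, %s (final change %.3g)\n",
    nrow(x$scores), ncol(x$scores), x$iterations,
    if (x$converged) "converged" else "NOT converged", x$delta
  ))
  invisible(x)
}

#' Score a dataset end to end
#'
#' Rebuilds the integrated, normalized similarities from a training
#' association matrix and runs the fixed-point propagation. This is the
#' unit of work repeated by every cross-validation round.
#'
#' @param dataset an [mda_dataset()].
#' @param A_train training association matrix (defaults to `dataset$A`).
#' @param params a [wmg_params()].
#' @return a `prediction_matrix` (see [propagate()]).
#' @export
wmg_score <- function(dataset, A_train = dataset$A, params = wmg_params()) {
  sims <- wmg_similarities(dataset, A_train, params)
  propagate(sims$DSn, sims$MSn, A_train, params)
}

#' Rank candidate microbes for one disease
#'
#' Sorts the microbes of one disease's score row in decreasing order, ties
#' broken by ascending microbe index so results are reproducible. Known
#' associations can be masked out so only candidates remain.
#'
#' @param P a `prediction_matrix` or a plain score matrix.
#' @param disease disease index or label.
#' @param exclude_known optional association matrix; microbes with a known
#'   association to the disease are dropped from the ranking.
#' @return data frame with columns `microbe`, `score`, `rank`.
#' @export
rank_candidates <- function(P, disease, exclude_known = NULL) {
  scores <- if (inherits(P, "prediction_matrix")) P$scores else P
  stopifnot(is.matrix(scores), all(is.finite(scores)))
  if (is.character(disease)) {
    disease <- match(disease, rownames(scores))
    if (is.na(disease)) stop("unknown disease label")
  }
  if (disease < 1 || disease > nrow(scores)) stop("disease index out of range")
  row <- scores[disease, ]
  keep <- seq_along(row)
  if (!is.null(exclude_known)) {
    stopifnot(all(dim(exclude_known) == dim(scores)))
    keep <- which(exclude_known[disease, ] == 0)
  }
  ids <- colnames(scores)
  if (is.null(ids)) ids <- paste0("m", seq_along(row))
  ord <- keep[order(-row[keep], keep)]
  data.frame(
    microbe = ids[ord],
    score = unname(row[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
}
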