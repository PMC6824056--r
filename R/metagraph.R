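#' The six weighted meta-graph patterns
#'
#' Enumerates the meta-graph templates used for scoring: all patterns on
#' the heterogeneous network schema with fewer than five edges or fewer
#' than three intermediate nodes. Exactly six exist: four single-path
#' patterns (a-d) and two dual-path patterns (e, f). Each pattern carries a
#' given-node count (nodes directly incident to the bipartite association
#' edge) and a bias rating reflecting its contribution potential.
#'
#' @param max_edges,max_intermediate the size caps defining the taxonomy;
#'   defaults 5 and 3 give the six standard patterns and other values are
#'   rejected as unsupported.
#' @param bias optional 6-vector of bias ratings attached to the patterns.
#' @return data frame with columns `pattern_id`, `given_nodes`, `arity`,
#'   `bias`.
#' @export
metagraph_patterns <- function(max_edges = 5, max_intermediate = 3,
                               bias = wmg_params()$bias) {
  if (max_edges != 5 || max_intermediate != 3) {
    stop("only the standard taxonomy (max_edges = 5, max_intermediate = 3) is supported")
  }
  stopifnot(length(bias) == 6L, all(bias >= 0), all(bias <= 1))
  data.frame(
    pattern_id = letters[1:6],
    given_nodes = c(2L, 1L, 1L, 0L, 1L, 1L),
    arity = c("single", "single", "single", "single", "dual", "dual"),
    bias = bias,
    stringsAsFactors = FALSE
  )
}

#' Literal per-pattern contribution to one pair (brute-force oracle)
#'
#' Evaluates the contribution of one meta-graph pattern to the pair
#' (disease i, microbe j) by exhaustively summing over all intermediate
#' node tuples, honoring the index-exclusion constraints of each pattern.
#' Quadratic loops; intended as the reference implementation against which
#' the matrix forms are verified.
#'
#' @param pattern_id one of `"a"` to `"f"`.
#' @param DS,MS integrated disease and microbe similarity matrices.
#' @param A association matrix.
#' @param i disease index, `j` microbe index.
#' @param j microbe index.
#' @return scalar contribution.
#' @export
pattern_contribution <- function(pattern_id, DS, MS, A, i, j) {
  stopifnot(nrow(DS) == nrow(A), ncol(DS) == nrow(A),
            nrow(MS) == ncol(A), ncol(MS) == ncol(A),
            i >= 1, i <= nrow(A), j >= 1, j <= ncol(A))
  nd <- nrow(A); nm <- ncol(A)
  switch(as.character(pattern_id),
    a = A[i, j],
    b = {
      s <- 0
      for (k in seq_len(nd)) if (k != i) s <- s + DS[i, k] * A[k, j]
      s
    },
    c = {
      s <- 0
      for (t in seq_len(nm)) if (t != j) s <- s + A[i, t] * MS[t, j]
      s
    },
    d = {
      s <- 0
      for (k in seq_len(nd)) {
        if (k == i) next
        for (t in seq_len(nm)) {
          if (t == j) next
          s <- s + DS[i, k] * A[k, t] * MS[t, j]
        }
      }
      s
    },
    e = {
      s <- 0
      for (k in seq_len(nd)) {
        if (k == i) next
        for (t in seq_len(nd)) {
          if (t == i || t == k) next
          s <- s + DS[i, k] * A[k, j] * DS[i, t] * A[t, j]
        }
      }
      s
    },
    f = {
      s <- 0
      for (k in seq_len(nm)) {
        if (k == j) next
        for (t in seq_len(nm)) {
          if (t == j || t == k) next
          s <- s + A[i, k] * MS[k, j] * A[i, t] * MS[t, j]
        }
      }
      s
    },
    stop("unknown pattern_id: ", pattern_id)
  )
}

# Identity subtraction of the fixed-point update, i.e. removal of the
# self-similarity edge. Identical to S - I for the unit-diagonal base
# similarities; for normalized inputs (diagonal below 1) the diagonal is
# zeroed instead of left negative, which preserves score nonnegativity and
# the index-sum semantics of the pattern contributions.
offdiag <- function(S) {
  diag(S) <- 0
  S
}

# Matrix-form pattern terms evaluated at score matrix P (the bracketed
# terms of the fixed-point update). Dual-path terms are returned before the
# gamma power and include the k = t diagonal that the index-sum forms
# exclude; `dual_path_diag_correction` quantifies that diagonal.
metagraph_terms <- function(DS, MS, A, P = A) {
  DSo <- offdiag(DS)
  MSo <- offdiag(MS)
  dp <- DSo %*% P
  pm <- P %*% MSo
  list(a = P, b = dp, c = pm, d = DSo %*% P %*% MSo, e = dp * dp, f = pm * pm)
}

# The k = t diagonal terms included by the squared matrix forms of the
# dual-path patterns but excluded by their index sums.
dual_path_diag_correction <- function(DS, MS, A, P = A) {
  DSo <- offdiag(DS)
  MSo <- offdiag(MS)
  list(e = (DSo * DSo) %*% (P * P), f = (P * P) %*% (MSo * MSo))
}

#' Single-pass weighted meta-graph score (brute-force oracle)
#'
#' Bias-weighted sum of the six pattern contributions for every pair, in
#' one pass (no iteration). Small instances only; this mirrors one
#' bracketed evaluation of the fixed-point update at `P = A` and serves as
#' the oracle for the iterative scorer.
#'
#' @param DS,MS integrated similarity matrices.
#' @param A association matrix.
#' @param params a [wmg_params()]; uses `bias` and `gamma`.
#' @param gamma_power apply the `gamma` exponent to the dual-path terms
#'   (default `TRUE`, mirroring the iterative update; `FALSE` gives the
#'   plain bias-weighted sum).
#' @param matrix_form use the squared matrix forms for the dual-path
#'   patterns (includes the k = t diagonal); `FALSE` (default) uses the
#'   exhaustive index sums that exclude it.
#' @return disease x microbe score matrix.
#' @export
brute_force_score <- function(DS, MS, A, params = wmg_params(),
                              gamma_power = TRUE, matrix_form = FALSE) {
  stopifnot(inherits(params, "wmg_params"))
  terms <- metagraph_terms(DS, MS, A, P = A)
  if (!matrix_form) {
    corr <- dual_path_diag_correction(DS, MS, A, P = A)
    terms$e <- terms$e - corr$e
    terms$f <- terms$f - corr$f
    terms$e[terms$e < 0] <- 0 # numerical guard; exact value is nonnegative
    terms$f[terms$f < 0] <- 0
  }
  if (gamma_power) {
    terms$e <- terms$e^params$gamma
    terms$f <- terms$f^params$gamma
  }
  out <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (l in 1:6) out <- out + params$bias[l] * terms[[l]]
  out
}
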