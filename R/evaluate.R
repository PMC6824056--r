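#' ROC curve and AUC by midrank counting
#'
#' AUC via the rank-sum formulation (equivalent to exhaustive concordant
#' pair counting with half credit for ties) plus the ROC polyline obtained
#' by sweeping the score threshold, grouping tied scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical), same length; both classes
#'   must be present.
#' @return list with `auc` and `roc_points` (data frame of `fpr`, `tpr`
#'   starting at (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores) # midranks for ties
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE) # close each tie group once
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(auc = auc, roc_points = roc)
}

# Normalized rank of one held-out score among its round's candidate scores:
# fraction of candidates scoring strictly above, plus half of the ties.
# The complement 1 - u is the round's contribution to the pooled AUC.
normalized_rank <- function(score, candidate_scores) {
  n <- length(candidate_scores)
  if (n == 0L) return(0)
  (sum(candidate_scores > score) + 0.5 * sum(candidate_scores == score)) / n
}

# Pooled evaluation summary from per-round normalized ranks and integer
# ranks (1 + number of candidates ranked above, midrank on ties).
pooled_eval_result <- function(u, ranks, n_candidates,
                               prf_ks = seq(0, 50, by = 5),
                               recovery_ks = c(10, 50, 100, 150, 200)) {
  stopifnot(length(u) == length(ranks))
  xs <- sort(unique(c(0, u, 1)))
  roc <- data.frame(fpr = xs, tpr = vapply(xs, function(x) mean(u <= x), 0))
  roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  roc <- roc[!duplicated(roc), , drop = FALSE]
  n_rounds <- length(ranks)
  prf_ks <- prf_ks[prf_ks > 0]
  prf <- data.frame(
    k = prf_ks,
    precision = vapply(prf_ks, function(k) sum(ranks <= k) / (k * n_rounds), 0),
    recall = vapply(prf_ks, function(k) sum(ranks <= k) / n_rounds, 0)
  )
  prf$f1 <- ifelse(prf$precision + prf$recall > 0,
                   2 * prf$precision * prf$recall / (prf$precision + prf$recall), 0)
  recovery <- data.frame(
    k = recovery_ks,
    recovered = vapply(recovery_ks, function(k) sum(ranks <= k), 0)
  )
  structure(
    list(auc = mean(1 - u), auc_std = NULL, roc_points = roc,
         normalized_ranks = u, ranks = ranks, n_candidates = n_candidates,
         prf_at_k = prf, recovery_at_k = recovery),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  if (is.null(x$auc_std)) {
    cat(sprintf("eval_result: AUC %.4f over %d rounds\n", x$auc, length(x$ranks)))
  } else {
    cat(sprintf("eval_result: AUC %.4f ±%.4f\n", x$auc, x$auc_std))
  }
  invisible(x)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is held out in turn: its entry is zeroed in the
#' training matrix, the interaction-profile kernels and integrated
#' similarities are recomputed from the reduced matrix, propagation is run,
#' and the held-out pair's score is ranked against all unverified pairs
#' (the global candidate set, pooled across diseases). The pooled rank
#' distribution yields the ROC curve, AUC, precision/recall/F1 table and
#' recovery counts.
#'
#' @param dataset an [mda_dataset()].
#' @param params a [wmg_params()].
#' @param per_disease rank each held-out pair only against the unverified
#'   pairs of its own disease instead of the pooled candidate set
#'   (non-default variant).
#' @param scorer scoring function `(dataset, A_train, params) ->
#'   score matrix`; the default runs the full pipeline ([wmg_score()]).
#'   Swapping in a null scorer (e.g. seeded random scores) gives the
#'   permutation baseline.
#' @return an `eval_result` (see [roc_auc()] and [pooled_eval_result]
#'   fields).
#' @export
global_loocv <- function(dataset, params = wmg_params(), per_disease = FALSE,
                         scorer = NULL) {
  stopifnot(inherits(dataset, "mda_dataset"))
  known <- which(dataset$A == 1)
  if (length(known) < 1L) stop("dataset has no known associations")
  if (is.null(scorer)) {
    scorer <- function(dataset, A_train, params) wmg_score(dataset, A_train, params)$scores
  }
  candidates_all <- which(dataset$A == 0)
  u <- ranks <- numeric(length(known))
  n_cand <- integer(length(known))
  for (idx in seq_along(known)) {
    pair <- known[idx]
    A_train <- dataset$A
    A_train[pair] <- 0
    stopifnot(A_train[pair] == 0)
    P <- scorer(dataset, A_train, params)
    cand <- if (per_disease) {
      i <- (pair - 1L) %% nrow(dataset$A) + 1L
      candidates_all[(candidates_all - 1L) %% nrow(dataset$A) + 1L == i]
    } else {
      candidates_all
    }
    u[idx] <- normalized_rank(P[pair], P[cand])
    ranks[idx] <- 1 + sum(P[cand] > P[pair]) + 0.5 * sum(P[cand] == P[pair])
    n_cand[idx] <- length(cand)
  }
  pooled_eval_result(u, ranks, n_cand)
}

#' Repeated k-fold cross-validation
#'
#' Per repetition the known associations are shuffled (repetition seed =
#' `cv$seed + repetition - 1`) and split into `cv$folds` groups; each group
#' is zeroed in turn, similarities are recomputed from the training matrix,
#' and the held-out pairs are ranked against the unverified pairs. Reports
#' the mean and standard deviation of the per-repetition pooled AUCs.
#'
#' @param dataset an [mda_dataset()].
#' @param params a [wmg_params()].
#' @param cv a [cv_config()].
#' @param scorer see [global_loocv()].
#' @return an `eval_result` with `auc` (mean), `auc_std`, `auc_per_rep`,
#'   and pooled rank-based tables from the final repetition.
#' @export
kfold_cv <- function(dataset, params = wmg_params(), cv = cv_config(),
                     scorer = NULL) {
  stopifnot(inherits(dataset, "mda_dataset"), inherits(cv, "cv_config"))
  known <- which(dataset$A == 1)
  if (cv$folds > length(known)) stop("more folds than known associations")
  if (is.null(scorer)) {
    scorer <- function(dataset, A_train, params) wmg_score(dataset, A_train, params)$scores
  }
  candidates_all <- which(dataset$A == 0)
  aucs <- numeric(cv$repetitions)
  last <- NULL
  for (rep_i in seq_len(cv$repetitions)) {
    set.seed(cv$seed + rep_i - 1L)
    fold_of <- sample(rep_len(seq_len(cv$folds), length(known)))
    u <- ranks <- numeric(length(known))
    n_cand <- integer(length(known))
    for (f in seq_len(cv$folds)) {
      held <- known[fold_of == f]
      A_train <- dataset$A
      A_train[held] <- 0
      stopifnot(all(A_train[held] == 0))
      P <- scorer(dataset, A_train, params)
      for (pair in held) {
        j <- which(known == pair)
        u[j] <- normalized_rank(P[pair], P[candidates_all])
        ranks[j] <- 1 + sum(P[candidates_all] > P[pair]) +
          0.5 * sum(P[candidates_all] == P[pair])
        n_cand[j] <- length(candidates_all)
      }
    }
    aucs[rep_i] <- mean(1 - u)
    last <- list(u = u, ranks = ranks, n_cand = n_cand)
  }
  out <- pooled_eval_result(last$u, last$ranks, last$n_cand)
  out$auc <- mean(aucs)
  out$auc_std <- if (cv$repetitions > 1) stats::sd(aucs) else NA_real_
  out$auc_per_rep <- aucs
  out
}

#' Cross-validation configuration
#'
#' @param scheme `"loocv"` or `"kfold"`.
#' @param folds number of folds for the k-fold scheme (default 5).
#' @param repetitions number of random re-divisions whose AUCs are averaged
#'   (default 100).
#' @param seed base seed; repetition r uses `seed + r - 1`.
#' @param robustness_mask_fraction fraction of known associations hidden
#'   before evaluation, in `[0, 1)` (default 0).
#' @return list of class `cv_config`.
#' @export
cv_config <- function(scheme = c("kfold", "loocv"), folds = 5L,
                      repetitions = 100L, seed = 1L,
                      robustness_mask_fraction = 0) {
  scheme <- match.arg(scheme)
  stopifnot(folds >= 2L, repetitions >= 1L,
            robustness_mask_fraction >= 0, robustness_mask_fraction < 1)
  structure(
    list(scheme = scheme, folds = as.integer(folds),
         repetitions = as.integer(repetitions), seed = as.integer(seed),
         robustness_mask_fraction = robustness_mask_fraction),
    class = "cv_config"
  )
}

#' Top-k precision, recall and F1 for a ranked candidate list
#'
#' @param ranked character or integer vector of candidate ids in rank
#'   order (best first).
#' @param truth ids of the true positives.
#' @param ks positive thresholds; values beyond the candidate count are
#'   clamped with a warning.
#' @return data frame with columns `k`, `precision`, `recall`, `f1`
#'   (F1 defined as 0 when precision and recall are both 0).
#' @export
precision_recall_f1_at_k <- function(ranked, truth, ks = seq(5, 50, by = 5)) {
  stopifnot(length(ks) > 0, all(ks > 0))
  if (any(ks > length(ranked))) {
    warning("threshold k exceeds candidate count; clamped")
  }
  kk <- pmin(ks, length(ranked))
  tp <- vapply(kk, function(k) sum(ranked[seq_len(k)] %in% truth), 0)
  precision <- tp / kk
  recall <- if (length(truth) > 0) tp / length(truth) else rep(0, length(kk))
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  data.frame(k = ks, precision = precision, recall = recall, f1 = f1)
}

#' Cumulative recovery counts of held-out associations
#'
#' @param loocv_ranks integer (or midrank) ranks of the held-out pairs,
#'   e.g. the `ranks` field of a [global_loocv()] result.
#' @param ks thresholds (default 10, 50, 100, 150, 200).
#' @return data frame `k`, `recovered`: how many held-out pairs ranked
#'   within the top k; nondecreasing in k.
#' @export
recovery_curve <- function(loocv_ranks, ks = c(10, 50, 100, 150, 200)) {
  stopifnot(is.numeric(loocv_ranks))
  data.frame(
    k = ks,
    recovered = vapply(ks, function(k) sum(loocv_ranks <= k), 0)
  )
}

#' Hide a fraction of known associations
#'
#' Robustness protocol: zeroes `floor(fraction * n_known)` known entries
#' chosen uniformly at random under the seed, returning the reduced dataset
#' with the list of hidden pairs attached.
#'
#' @param dataset an [mda_dataset()].
#' @param fraction fraction of knowns to hide, in `[0, 1)`.
#' @param seed RNG seed.
#' @return a new `mda_dataset`; attribute `"masked_pairs"` holds the linear
#'   indices of the zeroed entries.
#' @export
robustness_mask <- function(dataset, fraction, seed = 1L) {
  stopifnot(inherits(dataset, "mda_dataset"), fraction >= 0, fraction < 1)
  known <- which(dataset$A == 1)
  n_hide <- floor(fraction * length(known))
  A <- dataset$A
  hidden <- integer(0)
  if (n_hide > 0) {
    set.seed(seed)
    hidden <- sample(known, n_hide)
    A[hidden] <- 0
  }
  out <- mda_dataset(A, dags = dataset$dags,
                     FS = if (all(dataset$FS == diag(ncol(A)))) NULL else dataset$FS)
  attr(out, "masked_pairs") <- sort(hidden)
  out
}

#' New-disease prediction protocol
#'
#' Treats one disease as new: its entire association row is zeroed, the
#' similarities are recomputed (its kernel profile is then empty, so its
#' only links into the network are the DAG-derived semantic ones),
#' propagation is run, and all microbes are ranked for it. Returns the
#' fraction of its true microbes recovered within each top-k. A disease
#' with neither associations nor a DAG has no path into the network and is
#' rejected.
#'
#' @param dataset an [mda_dataset()].
#' @param disease disease label or index.
#' @param params a [wmg_params()].
#' @param ks thresholds; default `1:n_m` (full cumulative curve).
#' @return list with `ranking` (from [rank_candidates()]), `truth`
#'   (the zeroed-out microbe labels), and `recovery` (data frame `k`,
#'   `fraction` of truth within top k).
#' @export
new_disease_eval <- function(dataset, disease, params = wmg_params(), ks = NULL) {
  stopifnot(inherits(dataset, "mda_dataset"))
  if (is.character(disease)) {
    disease <- match(disease, rownames(dataset$A))
    if (is.na(disease)) stop("unknown disease label")
  }
  label <- rownames(dataset$A)[disease]
  has_dag <- !is.null(dataset$dags) && label %in% names(dataset$dags)
  if (!has_dag) {
    stop("disease '", label, "' has no DAG: without known associations or ",
         "DAG information its similarity to other diseases cannot be ",
         "obtained, so new-disease prediction is not possible")
  }
  truth <- colnames(dataset$A)[dataset$A[disease, ] == 1]
  A_train <- dataset$A
  A_train[disease, ] <- 0
  P <- wmg_score(dataset, A_train, params)
  ranking <- rank_candidates(P, disease)
  if (is.null(ks)) ks <- seq_len(ncol(dataset$A))
  frac <- vapply(ks, function(k) {
    if (length(truth) == 0) return(0)
    mean(truth %in% ranking$microbe[seq_len(min(k, nrow(ranking)))])
  }, 0)
  list(ranking = ranking, truth = truth,
       recovery = data.frame(k = ks, fraction = frac))
}
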