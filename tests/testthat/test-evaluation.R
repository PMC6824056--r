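test_that("ROC/AUC matches hand counting and exhaustive pair enumeration", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(5, 4, 3, 2), c(1, 1, 0, 0))$auc, 1)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    scores <- sample(seq_len(20), n, replace = TRUE) / 20 # plenty of ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels)$auc, auc_pairs(scores, labels))
  }
})

test_that("ROC polyline is a monotone path from (0,0) to (1,1)", {
  set.seed(32)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  pts <- roc_auc(scores, labels)$roc_points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- runif(150)
  labels <- rbinom(150, 1, 0.3)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("random scores give a chance-level AUC", {
  set.seed(34)
  aucs <- replicate(20, roc_auc(runif(400), rbinom(400, 1, 0.5))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("top-k precision/recall/F1 follow the standard definitions", {
  # 2 of the top 5 are true, 4 true overall
  tab <- precision_recall_f1_at_k(c("t1", "x", "t2", "y", "z", "t3"),
                                  c("t1", "t2", "t3", "t4"), ks = 5)
  expect_equal(tab$precision, 0.4)
  expect_equal(tab$recall, 0.5)
  expect_equal(tab$f1, 2 * 0.4 * 0.5 / 0.9)
  # all truth inside top-k
  tab <- precision_recall_f1_at_k(c("t1", "t2", "x", "y"), c("t1", "t2"), ks = 4)
  expect_equal(tab$precision, 0.5)
  expect_equal(tab$recall, 1)
  # no truth in top-k: everything 0, F1 defined as 0
  tab <- precision_recall_f1_at_k(c("x", "y"), "t1", ks = 2)
  expect_equal(unlist(tab[, c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
  expect_warning(precision_recall_f1_at_k(c("x", "y"), "x", ks = 10), "clamped")
})

test_that("recovery counts accumulate ranks correctly", {
  expect_equal(recovery_curve(c(3, 60, 110))$recovered, c(1, 1, 2, 3, 3))
  expect_equal(recovery_curve(rep(1, 7))$recovered, rep(7, 5))
  expect_equal(recovery_curve(c(300, 400))$recovered, rep(0, 5))
  expect_true(all(diff(recovery_curve(sample(1:250, 40))$recovered) >= 0))
})

test_that("robustness masking hides the exact fraction reproducibly", {
  ds <- planted_fixture()
  expect_equal(robustness_mask(ds, 0)$A, ds$A)
  n_known <- sum(ds$A)
  masked <- robustness_mask(ds, 0.1, seed = 5)
  expect_equal(sum(masked$A), n_known - floor(0.1 * n_known))
  expect_equal(attr(masked, "masked_pairs"),
               attr(robustness_mask(ds, 0.1, seed = 5), "masked_pairs"))
  expect_true(all(ds$A[attr(masked, "masked_pairs")] == 1))
})

test_that("LOOCV recomputes similarities per round and handles degenerate data", {
  # training matrix must have the held-out entry zeroed; verify via a
  # scorer that inspects its input
  ds <- planted_dataset(planted_spec(n_d = 4, n_m = 5, seed = 2))
  seen <- new.env()
  seen$ok <- TRUE
  probe <- function(dataset, A_train, params) {
    seen$ok <- seen$ok && (sum(dataset$A) - sum(A_train) == 1)
    matrix(runif(length(A_train)), nrow(A_train))
  }
  set.seed(35)
  global_loocv(ds, scorer = probe)
  expect_true(seen$ok)
  # a dataset with a single known pair completes the degenerate round
  A1 <- matrix(0, 3, 4)
  A1[2, 3] <- 1
  tiny <- mda_dataset(association_matrix(A1))
  res <- global_loocv(tiny)
  expect_true(is.finite(res$auc))
})

test_that("uniform random scoring yields chance-level LOOCV AUC", {
  ds <- planted_fixture()
  rand_scorer <- function(dataset, A_train, params) {
    matrix(runif(length(A_train)), nrow(A_train))
  }
  set.seed(36)
  aucs <- replicate(5, global_loocv(ds, scorer = rand_scorer)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("k-fold CV is seed-deterministic and consistent with LOOCV", {
  ds <- planted_fixture()
  cv1 <- cv_config(folds = 5, repetitions = 1, seed = 9)
  a <- kfold_cv(ds, cv = cv1)
  b <- kfold_cv(ds, cv = cv1)
  expect_identical(a$auc, b$auc)
  expect_error(kfold_cv(ds, cv = cv_config(folds = 500, repetitions = 1)),
               "more folds")
  kf <- kfold_cv(ds, cv = cv_config(folds = 5, repetitions = 3, seed = 1))
  loo <- global_loocv(ds)
  expect_lt(abs(kf$auc - loo$auc), 0.05)
  expect_true(is.finite(kf$auc_std))
})

test_that("entry-permuted associations drop k-fold CV to chance level", {
  ds <- planted_fixture()
  null_ds <- permute_associations(ds, seed = 11)
  kf <- kfold_cv(null_ds, cv = cv_config(folds = 5, repetitions = 3, seed = 2))
  expect_lt(abs(kf$auc - 0.5), 0.1)
})

test_that("new-disease protocol needs a DAG and recovers planted microbes", {
  ds <- planted_fixture()
  # strip the DAG of one disease: prediction for it must be refused
  dags <- ds$dags
  dags[["d1"]] <- NULL
  no_dag <- mda_dataset(ds$A, dags = dags, FS = ds$FS)
  expect_error(new_disease_eval(no_dag, "d1"), "no DAG")
  res <- new_disease_eval(ds, "d1")
  expect_gt(length(res$truth), 0)
  # full-length threshold recovers everything by construction
  expect_equal(res$recovery$fraction[ncol(ds$A)], 1)
  expect_true(all(diff(res$recovery$fraction) >= 0))
  # shared DAG ancestry pulls the true microbes into the top quarter
  k25 <- ceiling(0.25 * ncol(ds$A))
  expect_gt(res$recovery$fraction[k25], 0.5)
})
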