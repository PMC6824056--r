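# Fixture builders shared across tests. All randomness is seeded by the
# caller so every test is reproducible.

# random symmetric nonnegative similarity with unit diagonal
rand_sym_sim <- function(n, unit_diag = TRUE) {
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  if (unit_diag) diag(S) <- 1
  S
}

# random binary association matrix with at least one association
rand_assoc <- function(n_d, n_m, p = 0.4) {
  repeat {
    A <- matrix(rbinom(n_d * n_m, 1, p), n_d, n_m)
    if (sum(A) > 0) break
  }
  association_matrix(A)
}

# exhaustive concordant-pair AUC oracle: every positive/negative pair is
# counted, ties get half credit; independent of the rank-based route
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# the planted study dataset used by the end-to-end checks
planted_fixture <- function() planted_dataset(planted_spec(seed = 7))

# chain DAG root -> mid -> D used in the hand-computed examples
chain_dag <- function(id = "D", decay = 0.5) {
  disease_dag(id, data.frame(child = c(id, "mid"), parent = c("mid", "root")),
              decay = decay)
}
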