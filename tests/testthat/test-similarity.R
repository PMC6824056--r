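test_that("interaction-profile kernel matches hand evaluation and basic identities", {
  A <- association_matrix(diag(2))
  GD <- gip_kernel(A, "disease")
  expect_equal(GD[1, 2], exp(-2)) # bandwidth 1/mean(1,1) = 1, distance^2 = 2
  expect_equal(diag(GD), c(d1 = 1, d2 = 1))

  set.seed(11)
  A <- rand_assoc(6, 8)
  for (axis in c("disease", "microbe")) {
    K <- gip_kernel(A, axis)
    expect_equal(K, t(K))
    expect_true(all(K >= 0 & K <= 1))
    expect_equal(unname(diag(K)), rep(1, nrow(K)))
  }
  # identical profiles are maximally similar
  A2 <- A
  A2[2, ] <- A2[1, ]
  expect_equal(gip_kernel(association_matrix(A2), "disease")[1, 2], 1)
  # doubling the bandwidth multiplier squares every kernel entry
  K1 <- gip_kernel(A, "disease", bandwidth_mult = 1)
  K2 <- gip_kernel(A, "disease", bandwidth_mult = 2)
  expect_equal(K2, K1^2)
})

test_that("kernel is equivariant under simultaneous permutation of profiles", {
  set.seed(12)
  A <- rand_assoc(7, 5)
  perm <- sample(nrow(A))
  K <- gip_kernel(A, "disease")
  Kp <- gip_kernel(association_matrix(A[perm, ]), "disease")
  expect_equal(unname(Kp), unname(K[perm, perm]))
})

test_that("all-zero association matrix leaves the kernel bandwidth undefined", {
  A <- association_matrix(matrix(0, 3, 4))
  expect_error(gip_kernel(A, "disease"), "bandwidth is undefined")
  expect_error(gip_kernel(A, "microbe"), "bandwidth is undefined")
})

test_that("semantic values decay along the DAG and sum correctly", {
  sv <- semantic_value(chain_dag())
  expect_equal(sv$contrib, c(D = 1, mid = 0.5, root = 0.25))
  expect_equal(sv$sv, 1.75)
  # single-node DAG
  expect_equal(semantic_value(disease_dag("D"))$sv, 1)
  # diamond: two paths of lengths 1 and 2 to the root; max rule wins
  diamond <- disease_dag("D", data.frame(
    child = c("D", "D", "mid", "root"),
    parent = c("mid", "root", "root", "top")
  ))
  sv <- semantic_value(diamond)
  expect_equal(unname(sv$contrib["root"]), 0.5) # max(0.5 direct, 0.25 via mid)
})

test_that("invalid DAGs are rejected", {
  expect_error(
    disease_dag("D", data.frame(child = c("D", "x", "y"), parent = c("x", "y", "x"))),
    "cycle"
  )
  expect_error(
    disease_dag("D", data.frame(child = c("D", "stray"), parent = c("x", "y"))),
    "not ancestors"
  )
  expect_error(disease_dag("D", decay = 1.5), "decay")
})

test_that("semantic similarity follows the shared-credit formula", {
  d <- chain_dag()
  expect_equal(semantic_similarity(d, d), 1)
  # disjoint term sets
  a <- disease_dag("A", data.frame(child = "A", parent = "pa"))
  b <- disease_dag("B", data.frame(child = "B", parent = "pb"))
  expect_equal(semantic_similarity(a, b), 0)
  # one shared parent: (0.5 + 0.5) / (1.5 + 1.5)
  d1 <- disease_dag("D1", data.frame(child = "D1", parent = "P"))
  d2 <- disease_dag("D2", data.frame(child = "D2", parent = "P"))
  expect_equal(semantic_similarity(d1, d2), 1 / 3)
  expect_error(
    semantic_similarity(d1, disease_dag("D2", data.frame(child = "D2", parent = "P"),
                                        decay = 0.4)),
    "decay"
  )
})

test_that("cross-boundary functional similarity counts qualifying edges only", {
  fams <- c(a1 = "A", a2 = "A", b1 = "B", s = "both")
  one_cross <- gene_family_network(fams, data.frame(from = "a1", to = "b1"))
  expect_equal(functional_similarity(one_cross), 1)
  half <- gene_family_network(fams, data.frame(from = c("a1", "a1"), to = c("a2", "b1")))
  expect_equal(functional_similarity(half), 0.5)
  only_shared <- gene_family_network(fams, data.frame(from = c("a1", "b1"), to = c("s", "s")))
  expect_warning(s <- functional_similarity(only_shared), "set to 0")
  expect_equal(s, 0)
  # invariance under swapping the genome labels
  swapped <- gene_family_network(
    c(a1 = "B", a2 = "B", b1 = "A", s = "both"),
    data.frame(from = c("a1", "a1"), to = c("a2", "b1"))
  )
  expect_equal(functional_similarity(swapped), functional_similarity(half))
})

test_that("gene-family networks reject malformed input", {
  fams <- c(a = "A", b = "B")
  expect_error(gene_family_network(fams, data.frame(from = "a", to = "a")), "self-loop")
  expect_error(
    gene_family_network(fams, data.frame(from = c("a", "b"), to = c("b", "a"))),
    "duplicate"
  )
  expect_error(gene_family_network(c(a = "C"), data.frame(from = "a", to = "a")),
               "membership")
})

test_that("integrated similarities are convex blends with availability fallback", {
  set.seed(13)
  n <- 6
  SS <- rand_sym_sim(n)
  GD <- rand_sym_sim(n)
  expect_equal(integrate_disease_similarity(SS, GD, alpha = 0), GD)
  expect_equal(integrate_disease_similarity(SS, GD, alpha = 1), SS)
  # hand value from the worked fixtures
  SSh <- matrix(c(1, 1 / 3, 1 / 3, 1), 2)
  GDh <- matrix(c(1, exp(-2), exp(-2), 1), 2)
  DS <- integrate_disease_similarity(SSh, GDh, alpha = 0.6)
  expect_equal(DS[1, 2], 0.6 / 3 + 0.4 * exp(-2), tolerance = 1e-12)
  expect_equal(DS[1, 2], 0.25414, tolerance = 1e-4)
  # pair-level mask: uncovered pairs fall back to the kernel value
  mask <- matrix(FALSE, n, n)
  mask[1:2, 1:2] <- TRUE
  DSm <- integrate_disease_similarity(SS, GD, alpha = 0.6, semantic_defined = mask)
  expect_equal(DSm[1, 2], 0.6 * SS[1, 2] + 0.4 * GD[1, 2])
  expect_equal(DSm[3, 4], GD[3, 4])
  badmask <- mask
  badmask[1, 3] <- TRUE
  expect_error(integrate_disease_similarity(SS, GD, semantic_defined = badmask),
               "symmetric")
  # convexity bounds for both integrations
  FS <- rand_sym_sim(n); GM <- rand_sym_sim(n)
  MS <- integrate_microbe_similarity(FS, GM, beta = 0.7)
  expect_equal(MS[1, 2], 0.7 * FS[1, 2] + 0.3 * GM[1, 2])
  expect_equal(round(integrate_microbe_similarity(
    matrix(c(1, 0.5, 0.5, 1), 2), matrix(c(1, exp(-2), exp(-2), 1), 2), 0.7
  )[1, 2], 5), 0.39060)
  expect_equal(integrate_microbe_similarity(FS, GM, beta = 0), GM)
  expect_equal(integrate_microbe_similarity(FS, GM, beta = 1), FS)
  expect_true(all(MS >= pmin(FS, GM) - 1e-12 & MS <= pmax(FS, GM) + 1e-12))
  expect_error(integrate_microbe_similarity(FS, rand_sym_sim(n + 1)), "differ")
})

test_that("symmetric normalization rescales by row/column mass", {
  # constant row sums reduce to plain division
  S <- matrix(1, 4, 4)
  expect_equal(symmetric_normalize(S), S / 4)
  expect_equal(symmetric_normalize(matrix(5)), matrix(1))
  # isolated node keeps a zero row and column
  S <- rand_sym_sim(4)
  S[2, ] <- S[, 2] <- 0
  expect_warning(out <- symmetric_normalize(S), "zero")
  expect_equal(out[2, ], rep(0, 4))
  expect_equal(out[, 2], rep(0, 4))
  expect_error(symmetric_normalize(matrix(c(1, -1, -1, 1), 2)), "nonnegative")
})

test_that("normalized similarity has spectral radius at most one", {
  set.seed(14)
  for (rep in 1:10) {
    S <- rand_sym_sim(10, unit_diag = FALSE)
    out <- symmetric_normalize(S)
    expect_equal(out, t(out), tolerance = 1e-12)
    expect_lte(max(abs(eigen(out, only.values = TRUE)$values)), 1 + 1e-9)
  }
})

test_that("pipeline similarity rebuild degrades gracefully without associations", {
  ds <- planted_fixture()
  A0 <- ds$A
  A0[] <- 0
  sims <- wmg_similarities(ds, A0)
  # empty profiles: kernels are the identity, blends rest on priors alone
  expect_equal(unname(diag(sims$DS)), rep(1, nrow(A0)))
  expect_equal(sims$DS[1, 2], 0.6 * ds$SS[1, 2])
  expect_equal(sims$MS[1, 2], 0.7 * ds$FS[1, 2])
})
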