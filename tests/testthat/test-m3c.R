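sym_consensus <- function(vals) {
  # build a 4x4 consensus matrix from 6 upper-triangle values
  m <- diag(4)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("PAC analytic cases", {
  expect_equal(pac_score(sym_consensus(c(0, 1, 0, 1, 0, 1))), 0)
  expect_equal(pac_score(sym_consensus(rep(0.5, 6))), 1)
  expect_equal(pac_score(sym_consensus(c(0.05, 0.2, 0.5, 0.85, 0.95, 1.0))),
               0.5)                                  # 3 of 6 in (0.1, 0.9]
})

test_that("PAC decreases as ambiguous mass moves outside (U1, U2]", {
  vals <- c(0.3, 0.5, 0.6, 0.7, 0.2, 0.4)
  pac_full <- pac_score(sym_consensus(vals))
  for (k in 1:5) {
    moved <- vals
    moved[seq_len(k)] <- 0.05                        # push below U1
    expect_lte(pac_score(sym_consensus(moved)), pac_full)
  }
  # and the interval bounds behave as documented: (U1, U2] half-open
  expect_equal(pac_score(sym_consensus(rep(0.1, 6)), U1 = 0.1, U2 = 0.9), 0)
  expect_equal(pac_score(sym_consensus(rep(0.9, 6)), U1 = 0.1, U2 = 0.9), 1)
})

test_that("consensus on far-separated blobs is binary and deterministic", {
  X <- blob_matrix(n_per = 8, sep = 50)
  cfg <- m3c_config(n_consensus_iters = 30, seed = 5)
  cm <- consensus_cluster(X, 2, cfg)
  vals <- cm$consensus
  expect_true(all(vals %in% c(0, 1)))
  truth <- rep(1:2, each = 8)
  expect_true(all(vals[truth == 1, truth == 1] == 1))
  expect_true(all(vals[truth == 2, truth == 2] == 1))
  expect_equal(adjusted_rand_index(cm$labels, truth), 1)

  cm2 <- consensus_cluster(X, 2, cfg)
  expect_identical(cm$consensus, cm2$consensus)      # bitwise under fixed seed

  expect_error(consensus_cluster(X, 20, cfg), "exceeds|at least")
})

test_that("single-run consensus matches one direct PAM partition", {
  X <- blob_matrix(n_per = 3, sep = 30, seed = 12)   # N = 6
  cfg <- m3c_config(n_consensus_iters = 1, subsample_fraction = 0.999,
                    seed = 3)
  cm <- consensus_cluster(X, 2, cfg)
  direct <- cluster::pam(dist(X), 2, cluster.only = TRUE, pamonce = 3)
  expect_true(all(cm$consensus %in% c(0, 1)))
  expect_equal(cm$consensus[upper.tri(cm$consensus)],
               outer(direct, direct, "==")[upper.tri(diag(6))] + 0)
})

test_that("a never-co-sampled pair raises an informative error", {
  X <- blob_matrix(n_per = 10, sep = 10)
  cfg <- m3c_config(n_consensus_iters = 1, subsample_fraction = 0.5, seed = 1)
  expect_error(consensus_cluster(X, 2, cfg), "co-subsampled")
})

test_that("Gaussian reference datasets match mean and PC variance structure", {
  set.seed(8)
  X <- cbind(rnorm(40, 5, 3), rnorm(40, -2, 0.5), rnorm(40, 0, 1))
  X[, 2] <- X[, 2] + 0.8 * X[, 1]                    # correlated columns
  refs <- simulate_reference(X, n_sims = 100, seed = 4)
  expect_length(refs, 100)
  expect_identical(dim(refs[[1]]), dim(X))
  mean_err <- Reduce(`+`, lapply(refs, colMeans)) / 100 - colMeans(X)
  expect_true(all(abs(mean_err) < 0.5))
  pv_obs <- prcomp(X)$sdev^2
  pv_ref <- rowMeans(vapply(refs, function(R) prcomp(R)$sdev^2,
                            numeric(length(pv_obs))))
  expect_equal(pv_ref, pv_obs, tolerance = 0.1)
  expect_identical(simulate_reference(X, 1, seed = 4)[[1]], refs[[1]])
})

test_that("m3c_select_k: shape contract and planted-structure recovery", {
  X <- rbind(
    blob_matrix(n_per = 8, sep = 60, seed = 31),
    blob_matrix(n_per = 8, sep = 60, seed = 32) + 200
  )
  rownames(X) <- sprintf("x%02d", 1:32)
  truth <- rep(1:4, each = 8)
  cfg <- m3c_config(K_range = 2:6, n_consensus_iters = 40,
                    n_reference_sims = 40, seed = 7)
  res <- m3c_select_k(X, cfg)
  expect_identical(res$summary$K, 2:6)
  expect_identical(nrow(res$summary), 5L)
  expect_true(all(res$summary$pac >= 0 & res$summary$pac <= 1))
  expect_true(all(res$summary$p_value > 0 & res$summary$p_value <= 1))
  expect_length(res$per_K, 5)
  expect_true(4 %in% res$candidates)
  expect_gte(adjusted_rand_index(res$per_K$K4$labels, truth), 0.9)
})

test_that("local minimum rule: strict minima, boundaries need one lower neighbor", {
  lm <- routeclust:::local_minima
  expect_identical(lm(c(3, 1, 2, 1.5, 4)), c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(lm(c(1, 2, 3)), c(TRUE, FALSE, FALSE))
  expect_identical(lm(c(2, 2, 3)), c(FALSE, FALSE, FALSE))  # tie: not strict
})
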