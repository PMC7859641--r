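test_that("DTW analytic cases", {
  A <- matrix(c(0, 1, 0, 0), 2)
  expect_equal(dtw_distance(A, A), 0)
  B <- matrix(c(0, 1, 1, 1), 2)
  expect_equal(dtw_distance(A, B), 2)          # two unit pairings
  expect_error(dtw_distance(A, matrix(numeric(0), 0, 2)), "empty")
})

test_that("DTW equals the exhaustive warping-path oracle", {
  set.seed(101)
  for (i in 1:40) {
    A <- rand_path(sample(2:7, 1))
    B <- rand_path(sample(2:7, 1))
    expect_equal(dtw_distance(A, B), dtw_brute(A, B), tolerance = 1e-12)
  }
})

test_that("Frechet analytic cases and oracle equivalence", {
  A <- cbind(seq(0, 10, 2), 0)
  expect_equal(frechet_distance(A, A), 0)
  B <- cbind(seq(0, 10, 2), 3)                # parallel offset: constant leash
  expect_equal(frechet_distance(A, B), 3)

  set.seed(202)
  for (i in 1:40) {
    P <- rand_path(sample(2:8, 1))
    Q <- rand_path(sample(2:8, 1))
    expect_equal(frechet_distance(P, Q), frechet_oracle(P, Q),
                 tolerance = 1e-12)
  }
})

test_that("Frechet invariants: symmetry, triangle inequality, lower bound", {
  set.seed(303)
  for (i in 1:25) {
    P <- rand_path(sample(3:10, 1)); Q <- rand_path(sample(3:10, 1))
    R <- rand_path(sample(3:10, 1))
    pq <- frechet_distance(P, Q)
    expect_equal(pq, frechet_distance(Q, P), tolerance = 1e-12)
    expect_lte(pq, frechet_distance(P, R) + frechet_distance(R, Q) + 1e-9)
    lb <- max(euclid(P[1, ], Q[1, ]),
              euclid(P[nrow(P), ], Q[nrow(Q), ]))
    expect_gte(pq + 1e-12, lb)
  }
})

test_that("both measures are invariant under simultaneous rigid motion", {
  set.seed(404)
  P <- rand_path(12); Q <- rand_path(9)
  for (theta in c(0.4, 2.2)) {
    P2 <- rotate_pts(P, theta, c(7, -3)); Q2 <- rotate_pts(Q, theta, c(7, -3))
    expect_equal(dtw_distance(P2, Q2), dtw_distance(P, Q), tolerance = 1e-9)
    expect_equal(frechet_distance(P2, Q2), frechet_distance(P, Q),
                 tolerance = 1e-9)
  }
})

test_that("FastDTW upper-bounds exact DTW and is exact with a full window", {
  set.seed(55)
  for (i in 1:15) {
    A <- rand_path(sample(10:50, 1)); B <- rand_path(sample(10:50, 1))
    exact <- dtw_distance(A, B)
    approx_cost <- fastdtw_distance(A, B, radius = 1)
    expect_gte(approx_cost + 1e-9, exact)
    full <- fastdtw_distance(A, B, radius = max(nrow(A), nrow(B)))
    expect_equal(full, exact, tolerance = 1e-12)
  }
  expect_equal(fastdtw_distance(rand_path(30), rand_path(30) * 0 + 1, 0) >= 0,
               TRUE)
})

test_that("FastDTW default radius is within 5% on smooth resampled paths", {
  t1 <- resample_equal_arclength(wiggle_traj("a", n = 150, amp = 40), 6)
  t2 <- resample_equal_arclength(wiggle_traj("b", n = 150, amp = 25,
                                             phase = 0.7), 6)
  exact <- dtw_distance(t1, t2)
  fast <- fastdtw_distance(t1, t2, radius = 10)
  expect_gte(fast + 1e-9, exact)
  expect_lte(fast, exact * 1.05)
})

test_that("pairwise distance matrices: symmetry, zeros, step check, separation", {
  base <- wiggle_traj("a", n = 40)
  set <- trajectory_set(list(
    base,
    mirror_path(base, "y", bounds = c(0, 300)),   # far lateral twin
    wiggle_traj("c", n = 45, amp = 28, phase = 0.1)
  ))
  rset <- resample_set(set, 6)
  for (ms in c("dtw", "frechet")) {
    M <- pairwise_distance_matrix(rset, ms)
    expect_identical(M[2, 3], M[3, 2])        # mirrored bitwise
    expect_true(all(diag(unclass(M)) == 0))
    expect_true(all(unclass(M) >= 0))
  }
  ident <- pairwise_distance_matrix(list(rset[[1]], rset[[1]], rset[[1]]), "dtw")
  expect_true(all(unclass(ident) == 0))

  mixed <- rset; mixed[[2]] <- resample_equal_arclength(set[["c"]], 3)
  expect_error(pairwise_distance_matrix(mixed, "dtw"), "different steps")

  # two planted corridors far apart: within-route < between-route
  two <- generate_dataset(synthetic_config(
    routes = list(cbind(x = seq(0, 1400, 200), y = 60),
                  cbind(x = seq(0, 1400, 200), y = 240)),
    paths_per_route = 4, lateral_noise_sd = 4, waypoint_jitter_sd = 4,
    seed = 9))
  M <- pairwise_distance_matrix(resample_set(two$set, 6), "frechet")
  same <- outer(two$labels, two$labels, "==")
  up <- upper.tri(M)
  expect_lt(max(M[up & same]), min(M[up & !same]))
})

test_that("similarity description: normalization and concatenation contracts", {
  set <- trajectory_set(lapply(1:5, function(i) {
    wiggle_traj(paste0("t", i), n = 30 + i, amp = 5 * i, phase = i / 5)
  }))
  rset <- resample_set(set, 6)
  m1 <- pairwise_distance_matrix(rset, "dtw")
  m2 <- pairwise_distance_matrix(rset, "frechet")
  desc <- similarity_description(list(m1, m2))
  expect_identical(dim(unclass(desc)), c(5L, 10L))   # m * N columns
  v <- as.vector(unclass(desc))
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(min(v), 0)
  expect_equal(max(v), 1)
  # single measure: N columns, self-distances normalize to 0
  d1 <- similarity_description(m1)
  expect_identical(ncol(unclass(d1)), 5L)
  expect_true(all(diag(unclass(d1)) == 0))

  const <- m1; const[] <- 1; attr(const, "measure") <- "dtw"
  expect_error(similarity_description(list(const)), "degenerate")
})
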