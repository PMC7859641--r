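make_two_lane_model <- function(n_per = 5, mode = "similarity", sep = 200) {
  trajs <- list()
  for (i in seq_len(n_per)) {
    trajs[[length(trajs) + 1]] <-
      wiggle_traj(sprintf("lo%d", i), n = 40 + i, amp = 8, y0 = 50,
                  phase = i / 7)
    trajs[[length(trajs) + 1]] <-
      wiggle_traj(sprintf("hi%d", i), n = 40 + i, amp = 8, y0 = 50 + sep,
                  phase = i / 7)
  }
  set <- trajectory_set(trajs)
  labels <- setNames(rep(c(1L, 2L), n_per), traj_ids(set))
  rset <- resample_set(set, 6)
  if (mode == "similarity") {
    mats <- lapply(c("dtw", "frechet"),
                   function(ms) pairwise_distance_matrix(rset, ms))
    desc <- similarity_description(mats)
    model <- build_route_model(set, labels, desc, rset = rset,
                               measures = c("dtw", "frechet"))
  } else {
    desc <- suppressWarnings(characteristics_matrix(set))
    model <- build_route_model(set, labels, desc)
  }
  list(set = set, labels = labels, model = model, desc = desc)
}

test_that("t-SNE embedding: shape, determinism, separation, errors", {
  X <- blob_matrix(n_per = 10, sep = 60, seed = 44)
  e1 <- embed_tsne(X, seed = 2)
  e2 <- embed_tsne(X, seed = 2)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(20L, 2L))
  expect_true(all(is.finite(e1)))
  truth <- rep(1:2, each = 10)
  sil <- cluster::silhouette(truth, dist(e1))
  expect_gt(mean(sil[, "sil_width"]), 0)
  expect_error(embed_tsne(X, perplexity = 25), "perplexity")
  expect_error(embed_tsne(X[1:3, ]), "at least 4")
})

test_that("average_route: identity, symmetry, duplication invariance, oracle", {
  tr <- wiggle_traj("a", n = 30)
  avg1 <- average_route(list(tr), M = 50)
  expect_identical(dim(avg1), c(50L, 2L))
  expect_equal(avg1[c(1, 50), ], unname(tr$xy[c(1, 30), ]), ignore_attr = TRUE)

  up <- trajectory("u", seq(0, 10, 1), rep(1, 11))
  dn <- trajectory("d", seq(0, 10, 1), rep(-1, 11))
  mid <- average_route(list(up, dn), M = 20)
  expect_equal(unname(mid[, 2]), rep(0, 20))

  expect_equal(average_route(list(tr, tr, tr), M = 25),
               average_route(list(tr), M = 25))

  # two parallel offset arcs -> midline arc; hand-check at M = 5:
  # equal-length straight segments make fractional resampling analytic
  a <- trajectory("p", c(0, 4), c(0, 0))
  b <- trajectory("q", c(0, 8), c(2, 2))
  avg <- average_route(list(a, b), M = 5)
  # a resampled: x = 0,1,2,3,4; b: x = 0,2,4,6,8 -> mean x = 0,1.5,3,4.5,6
  expect_equal(unname(avg[, 1]), c(0, 1.5, 3, 4.5, 6))
  expect_equal(unname(avg[, 2]), rep(1, 5))
})

test_that("novel assignment in similarity mode: identity, perturbation, ties", {
  fix <- make_two_lane_model()
  model <- fix$model
  # a training member maps to its own cluster
  expect_identical(unname(assign_novel(fix$set[["lo3"]], model)),
                   fix$labels[["lo3"]])
  expect_identical(unname(assign_novel(fix$set[["hi2"]], model)),
                   fix$labels[["hi2"]])
  # small perturbation of a medoid stays in the medoid's cluster
  med <- fix$set[[model$medoid_ids[["2"]]]]
  pert <- trajectory("pert", med$xy[, 1], med$xy[, 2] + rnorm(nrow(med$xy), 0, 1))
  expect_identical(unname(assign_novel(pert, model)), 2L)
})

test_that("assignment is invariant under cluster relabeling", {
  fix <- make_two_lane_model()
  flipped <- setNames(3L - fix$labels, names(fix$labels))
  model2 <- build_route_model(fix$set, flipped, fix$desc,
                              rset = resample_set(fix$set, 6),
                              measures = c("dtw", "frechet"))
  novel <- fix$set[["lo1"]]
  k1 <- unname(assign_novel(novel, fix$model))
  k2 <- unname(assign_novel(novel, model2))
  expect_identical(k2, 3L - k1)
})

test_that("characteristics-mode assignment uses frozen training scaling", {
  fix <- make_two_lane_model(mode = "characteristics")
  expect_identical(unname(assign_novel(fix$set[["hi4"]], fix$model)), 2L)
  sc <- attr(fix$model$desc, "scaling")
  expect_length(sc$mean, 7)
  # degenerate novel path propagates the characteristics error
  expect_error(assign_novel(trajectory("bad", c(0, 1, 0), c(0, 1, 0)),
                            fix$model), "sinuosity")
})

test_that("equidistant novel path tie-breaks to the lowest cluster index", {
  fix <- make_two_lane_model()
  model <- fix$model
  X <- routeclust:::desc_values(model$desc)
  # synthetic tie: make both medoid rows identical, then any novel is a tie
  X[model$medoid_ids[["2"]], ] <- X[model$medoid_ids[["1"]], ]
  model$desc <- structure(X, mode_label = "similarity",
                          normalization = attr(model$desc, "normalization"),
                          class = class(model$desc))
  expect_identical(unname(assign_novel(fix$set[["hi1"]], model)), 1L)
})

test_that("plot_routes writes deterministic per-cluster panels", {
  fix <- make_two_lane_model(n_per = 3)
  dir <- withr::local_tempdir()
  files <- plot_routes(fix$set, fix$model, file.path(dir, "figs"))
  expect_identical(basename(files),
                   c("route_01.png", "route_02.png", "routes_all.png"))
  expect_true(all(file.exists(files)))
})
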