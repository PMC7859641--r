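#' Configuration for Monte Carlo consensus clustering
#'
#' @param K_range candidate numbers of routes (default 2:10).
#' @param n_consensus_iters subsampled clustering runs per K (default 100).
#' @param subsample_fraction fraction of trajectories drawn (without
#'   replacement) per run, in (0,1) (default 0.8).
#' @param n_reference_sims number of Gaussian reference datasets for the
#'   null PAC distribution (default 100).
#' @param U1,U2 bounds of the ambiguous consensus interval for the PAC score
#'   (defaults 0.1 and 0.9).
#' @param alpha significance level for candidate route numbers (default
#'   0.05).
#' @param seed integer seed; all Monte Carlo draws derive from it.
#' @return Named list of class `m3c_config`.
#' @export
m3c_config <- function(K_range = 2:10, n_consensus_iters = 100,
                       subsample_fraction = 0.8, n_reference_sims = 100,
                       U1 = 0.1, U2 = 0.9, alpha = 0.05, seed = 1) {
  stopifnot(min(K_range) >= 2, subsample_fraction > 0, subsample_fraction < 1,
            U1 >= 0, U1 < U2, U2 <= 1, n_consensus_iters >= 1,
            n_reference_sims >= 1)
  structure(
    list(K_range = as.integer(sort(unique(K_range))),
         n_consensus_iters = as.integer(n_consensus_iters),
         subsample_fraction = subsample_fraction,
         n_reference_sims = as.integer(n_reference_sims),
         U1 = U1, U2 = U2, alpha = alpha, seed = as.integer(seed)),
    class = "m3c_config"
  )
}

# One deterministic PAM run on a precomputed dissimilarity subset.
# FastPAM1 swap (pamonce = 3) with the deterministic BUILD initialization.
pam_labels <- function(dsub, K) {
  cluster::pam(dsub, k = K, diss = TRUE, cluster.only = TRUE,
               pamonce = 3, keep.diss = FALSE, keep.data = FALSE)
}

# Core consensus loop on a precomputed full dissimilarity matrix.
consensus_from_dist <- function(D, N, K, n_iters, frac, seed) {
  co_pair <- matrix(0, N, N)
  co_samp <- matrix(0, N, N)
  n_sub <- ceiling(frac * N)
  with_seed(seed, {
    for (it in seq_len(n_iters)) {
      idx <- sort(sample.int(N, n_sub))
      cl <- pam_labels(as.dist(D[idx, idx]), K)
      same <- outer(cl, cl, "==")
      co_pair[idx, idx] <- co_pair[idx, idx] + same
      co_samp[idx, idx] <- co_samp[idx, idx] + 1
    }
  })
  off <- upper.tri(co_samp)
  if (any(co_samp[off] == 0)) {
    stop("some trajectory pairs were never co-subsampled; ",
         "increase n_consensus_iters")
  }
  cm <- co_pair / pmax(co_samp, 1)
  diag(cm) <- 1
  list(consensus = cm, co_pair = co_pair, co_samp = co_samp)
}

#' Consensus matrix for one candidate number of routes
#'
#' Repeats `n_consensus_iters` times: subsample `ceiling(fraction * N)` rows
#' without replacement, cluster them with PAM (k-medoids, Euclidean in
#' description space, deterministic BUILD initialization), and record which
#' pairs co-cluster. The consensus index of a pair is its co-clustering
#' count divided by its co-sampling count — the empirical probability that
#' the two trajectories land in the same cluster. Final labels cut an
#' average-linkage dendrogram of (1 - consensus) into K groups, so the
#' labels reflect the same consensus that the PAC score judges.
#'
#' @param desc a `DescriptionMatrix`.
#' @param K number of clusters (>= 2, with at least 2K rows available).
#' @param cfg an [m3c_config()].
#' @return A `ConsensusMatrix`: list with `consensus` (N x N, diagonal 1),
#'   `labels` (named integer vector), `K`, and the raw `co_pair` /
#'   `co_samp` counts for reproducibility.
#' @export
consensus_cluster <- function(desc, K, cfg = m3c_config()) {
  X <- desc_values(desc)
  N <- nrow(X)
  if (K > N) stop("K = ", K, " exceeds the number of trajectories (", N, ")")
  if (N < 2 * K) stop("need at least 2*K = ", 2 * K, " trajectories, got ", N)
  D <- as.matrix(dist(X))
  res <- consensus_from_dist(D, N, K, cfg$n_consensus_iters,
                             cfg$subsample_fraction,
                             stage_seed(cfg$seed, paste0("consensus", K)))
  hc <- hclust(as.dist(1 - res$consensus), method = "average")
  labels <- setNames(cutree(hc, k = K), rownames(X))
  dimnames(res$consensus) <- list(rownames(X), rownames(X))
  structure(list(consensus = res$consensus, labels = labels, K = K,
                 co_pair = res$co_pair, co_samp = res$co_samp),
            class = "ConsensusMatrix")
}

#' @export
print.ConsensusMatrix <- function(x, ...) {
  cat(sprintf("<ConsensusMatrix K=%d> %d trajectories\n", x$K,
              nrow(x$consensus)))
  invisible(x)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of off-diagonal unordered pairs whose consensus index falls in
#' the ambiguous interval (U1, U2]: the middle segment of the consensus CDF.
#' An ideal clustering has indices only near 0 or 1, hence PAC 0; a fully
#' unstable one has indices near 0.5, hence PAC near 1. Lower is more
#' stable.
#'
#' @param cm a `ConsensusMatrix` or plain symmetric consensus matrix.
#' @param U1,U2 ambiguity bounds (defaults 0.1, 0.9).
#' @return PAC score in \[0, 1\].
#' @export
pac_score <- function(cm, U1 = 0.1, U2 = 0.9) {
  vals <- if (inherits(cm, "ConsensusMatrix")) cm$consensus else cm
  v <- vals[upper.tri(vals)]
  mean(v > U1 & v <= U2)
}

#' Simulate matched-covariance Gaussian reference datasets
#'
#' Each reference dataset has N rows drawn from a single multivariate
#' Gaussian whose principal-component variances match the input description
#' matrix: PC scores are sampled independently with the observed component
#' standard deviations, rotated back, and the column means re-added. These
#' datasets carry the input's overall shape but, by construction, a single
#' cluster — the null world against which observed PAC scores are tested.
#'
#' @param desc a `DescriptionMatrix` (N >= 3 rows).
#' @param n_sims number of reference datasets.
#' @param seed integer seed.
#' @return List of `n_sims` numeric matrices with the input's dimensions.
#' @export
simulate_reference <- function(desc, n_sims = 100, seed = 1) {
  X <- desc_values(desc)
  N <- nrow(X)
  stopifnot(N >= 3)
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  sdev <- pca$sdev
  rot <- pca$rotation
  mu <- colMeans(X)
  with_seed(seed, {
    lapply(seq_len(n_sims), function(i) {
      scores <- matrix(rnorm(N * length(sdev)), N) %*% diag(sdev, length(sdev))
      sweep(scores %*% t(rot), 2, mu, "+")
    })
  })
}

#' Select the number of routes by Monte Carlo consensus clustering
#'
#' For every K in `cfg$K_range`: computes the observed consensus matrix and
#' PAC score, consensus-clusters each Gaussian reference dataset at the same
#' K to build a null PAC distribution, and tests H0 "the PAC score comes
#' from a single Gaussian cluster" with the one-sided empirical p-value
#' `(1 + #\{null PAC <= observed PAC\}) / (1 + n_sims)` (smaller PAC = more
#' structure; the +1 pseudocount keeps p > 0). Candidate route numbers are
#' the Ks whose PAC is a local minimum over `K_range` (boundary Ks qualify
#' when lower than their single neighbor) and whose p-value is below
#' `cfg$alpha`. When several candidates exist all are reported — the
#' intended disambiguation is visual, via [embed_tsne()].
#'
#' @param desc a `DescriptionMatrix`.
#' @param cfg an [m3c_config()].
#' @return An `M3CResult`: list with `summary` (data.frame K, pac, p_value,
#'   is_local_min, candidate), `per_K` (consensus matrices, labels, null PAC
#'   samples), `candidates`, and `cfg`.
#' @export
m3c_select_k <- function(desc, cfg = m3c_config()) {
  X <- desc_values(desc)
  N <- nrow(X)
  refs <- simulate_reference(desc, cfg$n_reference_sims,
                             stage_seed(cfg$seed, "reference"))
  ref_dists <- lapply(refs, function(R) as.matrix(dist(R)))
  Ks <- cfg$K_range
  per_K <- vector("list", length(Ks))
  names(per_K) <- paste0("K", Ks)
  pac <- numeric(length(Ks))
  pvals <- numeric(length(Ks))
  for (ki in seq_along(Ks)) {
    K <- Ks[ki]
    obs <- consensus_cluster(desc, K, cfg)
    pac[ki] <- pac_score(obs, cfg$U1, cfg$U2)
    null_pac <- vapply(seq_along(ref_dists), function(r) {
      res <- consensus_from_dist(
        ref_dists[[r]], N, K, cfg$n_consensus_iters, cfg$subsample_fraction,
        stage_seed(cfg$seed, sprintf("null%d_%d", K, r))
      )
      pac_score(res$consensus, cfg$U1, cfg$U2)
    }, numeric(1))
    pvals[ki] <- (1 + sum(null_pac <= pac[ki])) / (1 + length(null_pac))
    per_K[[ki]] <- list(consensus = obs, pac = pac[ki],
                        null_pac = null_pac, p_value = pvals[ki],
                        labels = obs$labels)
  }
  is_min <- local_minima(pac)
  candidate <- is_min & (pvals < cfg$alpha)
  summary <- data.frame(K = Ks, pac = pac, p_value = pvals,
                        is_local_min = is_min, candidate = candidate)
  structure(list(summary = summary, per_K = per_K,
                 candidates = Ks[candidate], cfg = cfg),
            class = "M3CResult")
}

# Strict local minima; endpoints qualify if lower than their one neighbor.
local_minima <- function(v) {
  n <- length(v)
  if (n == 1) return(TRUE)
  left <- c(Inf, v[-n])
  right <- c(v[-1], Inf)
  v < left & v < right
}

#' @export
print.M3CResult <- function(x, ...) {
  cat("<M3CResult>\n")
  print(x$summary, row.names = FALSE)
  cat("candidate route numbers:",
      if (length(x$candidates)) paste(x$candidates, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
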