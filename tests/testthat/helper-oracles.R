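# Independent oracles and tiny fixture builders. The oracles deliberately
# avoid the package's dynamic programs: DTW is checked by exhaustive
# enumeration of every monotone warping path, discrete Frechet by a
# threshold-feasibility search over candidate leash lengths.

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Brute-force DTW: enumerate all monotone alignment paths from (1,1) to
# (n,m) and take the minimum summed cost. Exponential; for n,m <= 7 only.
dtw_brute <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  rec <- function(i, j) {
    d <- euclid(A[i, ], B[j, ])
    if (i == n && j == m) return(d)
    branches <- c(
      if (i < n) rec(i + 1, j),
      if (j < m) rec(i, j + 1),
      if (i < n && j < m) rec(i + 1, j + 1)
    )
    d + min(branches)
  }
  rec(1, 1)
}

# Discrete Frechet oracle: the answer is one of the pairwise point
# distances; find the smallest candidate eps for which a monotone coupling
# staying within eps exists (forward reachability sweep on the grid).
frechet_oracle <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  D <- outer(seq_len(n), seq_len(m),
             Vectorize(function(i, j) euclid(A[i, ], B[j, ])))
  feasible <- function(eps) {
    ok <- D <= eps
    if (!ok[1, 1]) return(FALSE)
    reach <- matrix(FALSE, n, m)
    reach[1, 1] <- TRUE
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        if (i == 1 && j == 1) next
        if (!ok[i, j]) next
        from <- (i > 1 && reach[i - 1, j]) || (j > 1 && reach[i, j - 1]) ||
          (i > 1 && j > 1 && reach[i - 1, j - 1])
        reach[i, j] <- from
      }
    }
    reach[n, m]
  }
  for (eps in sort(unique(as.vector(D)))) {
    if (feasible(eps)) return(eps)
  }
  stop("unreachable")
}

rand_path <- function(len, scale = 10) {
  matrix(runif(2 * len, -scale, scale), ncol = 2)
}

# A smooth wiggly trajectory crossing a tunnel; deterministic given its args.
wiggle_traj <- function(id = "t1", n = 60, amp = 30, y0 = 150, phase = 0,
                        frame_rate = 60) {
  x <- seq(0, 1400, length.out = n)
  y <- y0 + amp * sin(x / 150 + phase)
  trajectory(id, x, y, frame_rate = frame_rate)
}

# Two far-separated Gaussian blobs in description space.
blob_matrix <- function(n_per = 10, d = 4, sep = 40, sd = 1, seed = 99) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per * d, 0, sd), n_per),
    matrix(rnorm(n_per * d, sep, sd), n_per)
  )
  rownames(X) <- sprintf("b%02d", seq_len(2 * n_per))
  X
}

rotate_pts <- function(P, theta, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(P %*% t(R), 2, shift, "+")
}
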