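as_point_matrix <- function(p) {
  if (inherits(p, "ResampledTrajectory") || inherits(p, "Trajectory")) p <- p$xy
  p <- as.matrix(p)
  if (nrow(p) == 0) stop("empty point sequence")
  if (ncol(p) != 2) stop("point sequences must be n x 2 matrices")
  if (!all(is.finite(p))) stop("non-finite coordinates in point sequence")
  storage.mode(p) <- "double"
  p
}

#' Exact dynamic time warping distance
#'
#' Minimum, over all monotone non-crossing alignments that pair the first and
#' last points of both sequences, of the summed Euclidean point-pair
#' distances (the classic O(|A||B|) dynamic program). A global measure of
#' path similarity: every point of both paths contributes. The total cost is
#' not normalized by path length; length effects are mitigated upstream by
#' constant-step resampling.
#'
#' @param A,B point sequences: n x 2 matrices, `Trajectory` or
#'   `ResampledTrajectory` objects.
#' @return Nonnegative distance (mm-summed).
#' @export
dtw_distance <- function(A, B) {
  dtw_cost_cpp(as_point_matrix(A), as_point_matrix(B))
}

#' Discrete Frechet distance
#'
#' Minimum over monotone couplings of the maximum paired Euclidean distance
#' ("shortest sufficient leash") between two ordered point sequences — a
#' local, extremum-based measure of path similarity. On densely resampled
#' paths it approximates the continuous Frechet distance to within one
#' resampling step.
#'
#' @inheritParams dtw_distance
#' @return Nonnegative distance (mm).
#' @export
frechet_distance <- function(A, B) {
  frechet_cost_cpp(as_point_matrix(A), as_point_matrix(B))
}

# FastDTW ----------------------------------------------------------------

# Average consecutive point pairs; odd length keeps the last point.
halve_path <- function(p) {
  n <- nrow(p)
  half <- floor(n / 2)
  idx <- seq_len(half) * 2
  q <- (p[idx - 1, , drop = FALSE] + p[idx, , drop = FALSE]) / 2
  if (n %% 2 == 1) q <- rbind(q, p[n, , drop = FALSE])
  q
}

# Windowed DTW over contiguous per-row column ranges [lo_i, hi_i].
# Returns cost and the optimal warping path (k x 2 index matrix).
dtw_window <- function(A, B, lo, hi) {
  n <- nrow(A); m <- nrow(B)
  cost <- vector("list", n)
  back <- vector("list", n)
  for (i in seq_len(n)) {
    jj <- lo[i]:hi[i]
    dx <- A[i, 1] - B[jj, 1]; dy <- A[i, 2] - B[jj, 2]
    d <- sqrt(dx * dx + dy * dy)
    crow <- numeric(length(jj)); brow <- integer(length(jj))
    for (k in seq_along(jj)) {
      j <- jj[k]
      cands <- c(Inf, Inf, Inf)   # 1 = diag, 2 = up, 3 = left
      if (i == 1 && j == 1) {
        cands[1] <- 0
      } else {
        if (i > 1) {
          prev_jj <- lo[i - 1]:hi[i - 1]
          pk <- match(j - 1, prev_jj)
          if (!is.na(pk)) cands[1] <- cost[[i - 1]][pk]
          pk <- match(j, prev_jj)
          if (!is.na(pk)) cands[2] <- cost[[i - 1]][pk]
        }
        if (k > 1) cands[3] <- crow[k - 1]
      }
      brow[k] <- which.min(cands)
      crow[k] <- d[k] + cands[brow[k]]
    }
    cost[[i]] <- crow
    back[[i]] <- brow
  }
  if (!is.finite(cost[[n]][hi[n] - lo[n] + 1])) {
    stop("window does not connect the endpoints")   # cannot happen for valid windows
  }
  path <- matrix(0L, n + m, 2)
  i <- n; j <- m; step <- 0L
  while (TRUE) {
    step <- step + 1L
    path[step, ] <- c(i, j)
    if (i == 1 && j == 1) break
    mv <- back[[i]][j - lo[i] + 1]
    if (mv == 1) { i <- i - 1; j <- j - 1 }
    else if (mv == 2) i <- i - 1
    else j <- j - 1
  }
  list(cost = cost[[n]][hi[n] - lo[n] + 1],
       path = path[step:1, , drop = FALSE])
}

full_window <- function(n, m) list(lo = rep(1L, n), hi = rep(m, n))

# Project a coarse warping path to the finer grid and inflate by `radius`.
expand_window <- function(path, n, m, radius) {
  lo <- rep.int(m + 1L, n); hi <- rep.int(0L, n)
  for (r in seq_len(nrow(path))) {
    is_ <- pmin(n, c(2L * path[r, 1] - 1L, 2L * path[r, 1]))
    js <- pmin(m, c(2L * path[r, 2] - 1L, 2L * path[r, 2]))
    for (i in unique(is_)) {
      lo[i] <- min(lo[i], js[1]); hi[i] <- max(hi[i], js[2])
    }
  }
  # rows skipped by the projection inherit their neighbors' span
  for (i in seq_len(n)) {
    if (hi[i] == 0L) { lo[i] <- lo[i - 1]; hi[i] <- hi[i - 1] }
  }
  if (radius > 0) {
    lo2 <- lo; hi2 <- hi
    for (i in seq_len(n)) {
      rng <- max(1, i - radius):min(n, i + radius)
      lo2[i] <- max(1L, min(lo[rng]) - radius)
      hi2[i] <- min(m, max(hi[rng]) + radius)
    }
    lo <- lo2; hi <- hi2
  }
  # windows must be monotone staircases so the DP can traverse them
  for (i in seq_len(n)[-1]) {
    lo[i] <- max(lo[i], lo[i - 1])
    hi[i] <- max(hi[i], hi[i - 1])
  }
  list(lo = lo, hi = hi)
}

fastdtw_rec <- function(A, B, radius) {
  n <- nrow(A); m <- nrow(B)
  if (n <= radius + 2 || m <= radius + 2) {
    w <- full_window(n, m)
    return(dtw_window(A, B, w$lo, w$hi))
  }
  coarse <- fastdtw_rec(halve_path(A), halve_path(B), radius)
  w <- expand_window(coarse$path, n, m, radius)
  dtw_window(A, B, w$lo, w$hi)
}

#' FastDTW approximate dynamic time warping
#'
#' Multilevel coarsen-project-refine approximation: the path is solved at
#' half resolution, projected up, and refined within a window inflated by
#' `radius` cells. The returned cost is that of a feasible warping path and
#' therefore always >= [dtw_distance()]; with `radius >= max(|A|, |B|)` the
#' window is full and the result is exact. The approximation exists purely
#' for speed on long paths.
#'
#' @inheritParams dtw_distance
#' @param radius nonnegative integer window inflation (default 10).
#' @return Nonnegative distance.
#' @export
fastdtw_distance <- function(A, B, radius = 10) {
  stopifnot(radius >= 0, radius == round(radius))
  fastdtw_rec(as_point_matrix(A), as_point_matrix(B), as.integer(radius))$cost
}

# Distance matrices -------------------------------------------------------

#' All-pairs path distance matrix
#'
#' Computes the upper triangle only and mirrors it; the diagonal is exactly
#' zero. All inputs must share the same resampling step so distances are
#' commensurate.
#'
#' @param rset list of `ResampledTrajectory` (from [resample_set()]).
#' @param measure `"dtw"` (exact), `"frechet"`, or `"fastdtw"`.
#' @param radius FastDTW radius (used only for `measure = "fastdtw"`).
#' @return A `DistanceMatrix`: symmetric N x N numeric matrix with trajectory
#'   ids as dimnames and attribute `measure`.
#' @export
pairwise_distance_matrix <- function(rset, measure = c("dtw", "frechet", "fastdtw"),
                                     radius = 10) {
  measure <- match.arg(measure)
  stopifnot(length(rset) >= 2)
  steps <- vapply(rset, `[[`, numeric(1), "step_mm")
  if (diff(range(steps)) > 1e-12 * max(steps)) {
    stop("trajectories were resampled with different steps: ",
         paste(signif(unique(steps), 6), collapse = ", "))
  }
  ids <- vapply(rset, `[[`, character(1), "traj_id")
  paths <- lapply(rset, `[[`, "xy")
  if (measure %in% c("dtw", "frechet")) {
    vals <- pairwise_cost_cpp(paths, if (measure == "dtw") 0L else 1L)
  } else {
    n <- length(paths)
    vals <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        vals[i, j] <- vals[j, i] <- fastdtw_distance(paths[[i]], paths[[j]],
                                                     radius = radius)
      }
    }
  }
  dimnames(vals) <- list(ids, ids)
  structure(vals, measure = measure,
            class = c("DistanceMatrix", "matrix", "array"))
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("<DistanceMatrix [%s]> %d x %d\n", attr(x, "measure"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Concatenated similarity description matrix
#'
#' Each distance matrix is min-max normalized to \[0, 1\] over all its
#' entries (the two measures — a sum and a maximum — have incommensurate
#' scales), then row i of every matrix is concatenated: with m measures and N
#' trajectories each trajectory is described by its normalized distance to
#' every trajectory under every measure, an m*N-dimensional feature vector.
#'
#' @param matrices list of `DistanceMatrix` sharing ids and order.
#' @return N x (m*N) `DescriptionMatrix` with attribute `normalization`
#'   recording each measure's min and max (frozen for novel-path
#'   assignment).
#' @export
similarity_description <- function(matrices) {
  if (inherits(matrices, "DistanceMatrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  ids <- rownames(matrices[[1]])
  norms <- list()
  blocks <- lapply(matrices, function(mat) {
    if (!identical(rownames(mat), ids)) {
      stop("distance matrices do not share trajectory ids/order")
    }
    rng <- range(mat)
    if (rng[1] == rng[2]) {
      stop("constant distance matrix (", attr(mat, "measure"),
           "): min-max normalization is degenerate")
    }
    measure <- attr(mat, "measure")
    norms[[measure]] <<- list(min = rng[1], max = rng[2])
    scaled <- (desc_values(mat) - rng[1]) / (rng[2] - rng[1])
    colnames(scaled) <- paste(measure, ids, sep = ".")
    scaled
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- ids
  structure(out, mode_label = "similarity", normalization = norms,
            class = c("DescriptionMatrix", "matrix", "array"))
}
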