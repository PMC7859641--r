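#' Pairwise co-clustering confusion matrix
#'
#' Compares an alternative clustering to a reference over all unordered
#' trajectory pairs: co-clustered in both = TP; separated in both = TN;
#' co-clustered only in the reference = FN; only in the alternative = FP.
#' Invariant under relabeling of either clustering.
#'
#' @param ref_labels,alt_labels named integer vectors over the same ids.
#' @return Named integer vector `c(TP, FP, TN, FN)` of class
#'   `PairConfusion`; the four counts sum to `N (N - 1) / 2`.
#' @export
coclustering_confusion <- function(ref_labels, alt_labels) {
  ids <- names(ref_labels)
  if (!setequal(ids, names(alt_labels))) {
    only_ref <- setdiff(ids, names(alt_labels))
    only_alt <- setdiff(names(alt_labels), ids)
    stop("label id mismatch; only in reference: ",
         paste(only_ref, collapse = ", "), "; only in alternative: ",
         paste(only_alt, collapse = ", "))
  }
  alt_labels <- alt_labels[ids]
  up <- upper.tri(diag(length(ids)))
  same_ref <- outer(ref_labels, ref_labels, "==")[up]
  same_alt <- outer(alt_labels, alt_labels, "==")[up]
  structure(
    c(TP = sum(same_ref & same_alt), FP = sum(!same_ref & same_alt),
      TN = sum(!same_ref & !same_alt), FN = sum(same_ref & !same_alt)),
    class = "PairConfusion"
  )
}

#' Precision of pairwise co-clustering
#'
#' TP / (TP + FP): of the pairs the alternative clustering puts together,
#' the fraction the reference also puts together. 1 means every co-clustered
#' pair agrees with the reference.
#'
#' @param conf a `PairConfusion` from [coclustering_confusion()].
#' @return Precision in \[0, 1\].
#' @export
precision <- function(conf) {
  tp <- conf[["TP"]]; fp <- conf[["FP"]]
  if (tp + fp == 0) {
    stop("precision undefined: the alternative clustering has no ",
         "co-clustered pairs (TP + FP = 0)")
  }
  tp / (tp + fp)
}

#' Random-clustering null distribution of the precision score
#'
#' Simulates random clusterings: per simulation a cluster count K is drawn
#' uniformly from `K_range` and every trajectory is assigned independently
#' and uniformly to one of the K clusters (empty clusters may occur).
#' Precision against `ref_labels` is recorded for each, giving the null
#' distribution an observed precision is judged against.
#'
#' @param ref_labels named integer reference labels.
#' @param K_range cluster counts to draw from (default 2:10).
#' @param n_sims number of random clusterings (default 100).
#' @param seed integer seed.
#' @return List with `null` (numeric vector), `critical` (95th percentile),
#'   and `p_value(t)`, the upper-tail probability
#'   `(1 + #\{null >= t\}) / (1 + n_sims)`.
#' @export
random_precision_null <- function(ref_labels, K_range = 2:10, n_sims = 100,
                                  seed = 1) {
  stopifnot(n_sims >= 1)
  n <- length(ref_labels)
  null <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      K <- if (length(K_range) == 1) K_range else sample(K_range, 1)
      rnd <- setNames(sample.int(K, n, replace = TRUE), names(ref_labels))
      precision(coclustering_confusion(ref_labels, rnd))
    }, numeric(1))
  })
  list(
    null = null,
    critical = unname(quantile(null, 0.95)),
    p_value = function(t) (1 + sum(null >= t)) / (1 + n_sims)
  )
}

#' Robustness of the clustering to the resampling coefficient
#'
#' Reruns the full similarity + consensus pipeline for every resampling
#' coefficient `s` and compares, per candidate K, the resulting partition
#' with the reference run (`s = reference_step`) via the pairwise precision
#' score; each precision is also judged against the random-clustering null.
#' One seed is shared across `s` values so differences reflect `s`, not
#' Monte Carlo noise. Only consensus labels are needed per (s, K) — the
#' Gaussian reference test is not re-run inside the sweep.
#'
#' @param set a `TrajectorySet`.
#' @param steps resampling coefficients to test (default 2:11 mm/step).
#' @param reference_step reference coefficient (default 6 mm/step).
#' @param cfg an [m3c_config()] (its `K_range`, iteration count and seed are
#'   used).
#' @param measures similarity measures (default `c("dtw", "frechet")`).
#' @param n_null_sims random clusterings per null (default 100).
#' @return A `RobustnessResult`: list with `table` (data.frame s, K,
#'   precision, null_critical, p_value), `reference_step`, `nulls` (per-K
#'   null objects) and `labels` (per s, per K).
#' @export
resampling_sweep <- function(set, steps = 2:11, reference_step = 6,
                             cfg = m3c_config(), measures = c("dtw", "frechet"),
                             n_null_sims = 100) {
  stopifnot(inherits(set, "TrajectorySet"))
  all_steps <- union(reference_step, steps)
  run_at <- function(s) {
    rset <- resample_set(set, step_mm = s)
    mats <- lapply(measures, function(ms) pairwise_distance_matrix(rset, ms))
    desc <- similarity_description(mats)
    labs <- lapply(cfg$K_range, function(K) consensus_cluster(desc, K, cfg)$labels)
    names(labs) <- paste0("K", cfg$K_range)
    labs
  }
  runs <- lapply(all_steps, run_at)
  names(runs) <- as.character(all_steps)
  ref <- runs[[as.character(reference_step)]]
  nulls <- lapply(seq_along(cfg$K_range), function(ki) {
    random_precision_null(ref[[ki]], K_range = cfg$K_range,
                          n_sims = n_null_sims,
                          seed = stage_seed(cfg$seed, paste0("null_prec", ki)))
  })
  names(nulls) <- paste0("K", cfg$K_range)
  rows <- list()
  for (s in steps) {
    alt <- runs[[as.character(s)]]
    for (ki in seq_along(cfg$K_range)) {
      prec <- precision(coclustering_confusion(ref[[ki]], alt[[ki]]))
      rows[[length(rows) + 1]] <- data.frame(
        s = s, K = cfg$K_range[ki], precision = prec,
        null_critical = nulls[[ki]]$critical,
        p_value = nulls[[ki]]$p_value(prec)
      )
    }
  }
  structure(
    list(table = do.call(rbind, rows), reference_step = reference_step,
         nulls = nulls, labels = runs),
    class = "RobustnessResult"
  )
}

#' @export
print.RobustnessResult <- function(x, ...) {
  cat(sprintf("<RobustnessResult> reference s = %g mm/step\n",
              x$reference_step))
  print(utils::head(x$table, 12), row.names = FALSE)
  if (nrow(x$table) > 12) cat("...", nrow(x$table), "rows\n")
  invisible(x)
}
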