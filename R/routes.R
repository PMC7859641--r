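#' t-SNE embedding of the description space
#'
#' Projects the high-dimensional trajectory descriptions to 2D with
#' t-distributed stochastic neighbor embedding for visual validation of
#' candidate route numbers. Defaults favor stability over flash: exact
#' (theta = 0) gradients, PCA initialization, fixed seed — the embedding
#' arbitrates between candidate Ks, so it must not move between runs.
#'
#' @param desc a `DescriptionMatrix` with N >= 4 rows.
#' @param perplexity t-SNE perplexity; default `min(30, (N - 1) / 3)`. Must
#'   be < N.
#' @param seed integer seed.
#' @param max_iter gradient iterations (default 1000).
#' @return N x 2 matrix of embedding coordinates, rownames = trajectory ids.
#' @export
embed_tsne <- function(desc, perplexity = NULL, seed = 1, max_iter = 1000) {
  X <- desc_values(desc)
  N <- nrow(X)
  if (N < 4) stop("t-SNE needs at least 4 trajectories")
  if (is.null(perplexity)) perplexity <- min(30, (N - 1) / 3)
  if (perplexity >= N) stop("perplexity (", perplexity,
                            ") must be smaller than N (", N, ")")
  Y <- with_seed(seed, {
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, theta = 0,
                 pca = TRUE, partial_pca = FALSE, max_iter = max_iter,
                 verbose = FALSE, check_duplicates = FALSE,
                 num_threads = 1)$Y
  })
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

# Resample a path to exactly M points at fractional arc-length positions
# j/(M-1) of its total length.
resample_to_m <- function(xy, M) {
  xy <- collapse_repeats(as_point_matrix(xy))
  total <- sum(sqrt(rowSums(diff(xy)^2)))
  if (total <= 0) stop("degenerate path: zero arc length")
  interp_at_arclength(xy, seq(0, total, length.out = M))
}

#' Average route of a set of member trajectories
#'
#' Each member is resampled to exactly M points equally spaced in fractional
#' arc length (positions j/(M-1) of its own total length), so members of
#' different lengths contribute M aligned points; the average route is the
#' pointwise mean.
#'
#' @param members list of `Trajectory` (or point matrices).
#' @param M number of points of the average polyline (default 100).
#' @return M x 2 matrix.
#' @export
average_route <- function(members, M = 100) {
  stopifnot(length(members) >= 1, M >= 2)
  resampled <- lapply(members, function(tr) {
    xy <- if (inherits(tr, "Trajectory") || inherits(tr, "ResampledTrajectory"))
      tr$xy else tr
    resample_to_m(xy, M)
  })
  Reduce(`+`, resampled) / length(resampled)
}

#' Build a route model from a clustering
#'
#' Bundles everything needed to plot routes and assign novel trajectories:
#' the labels, one medoid per cluster (the member minimizing the summed
#' Euclidean distance to its cluster in description space), per-cluster
#' average routes, and the frozen normalization constants of the
#' description. Nothing is re-fit at assignment time.
#'
#' @param set the training `TrajectorySet`.
#' @param labels named integer vector `traj_id -> cluster`.
#' @param desc the `DescriptionMatrix` the labels were derived from.
#' @param rset the resampled training set (required for `"similarity"`
#'   descriptions; its `step_mm` attribute and measures are reused for novel
#'   paths).
#' @param measures character vector of measures used to build `desc`
#'   (similarity mode), e.g. `c("dtw", "frechet")`.
#' @param M points per average route (default 100).
#' @return A `RouteModel`.
#' @export
build_route_model <- function(set, labels, desc, rset = NULL, measures = NULL,
                              M = 100) {
  stopifnot(inherits(set, "TrajectorySet"))
  ids <- traj_ids(set)
  if (!all(ids %in% names(labels))) stop("labels must cover every trajectory")
  labels <- labels[ids]
  mode <- attr(desc, "mode_label")
  if (mode == "similarity" && (is.null(rset) || is.null(measures))) {
    stop("similarity-mode models need the resampled set and measure list")
  }
  X <- desc_values(desc)
  clusters <- sort(unique(labels))
  medoid_ids <- vapply(clusters, function(k) {
    member_ids <- ids[labels == k]
    sub <- X[member_ids, , drop = FALSE]
    D <- as.matrix(dist(sub))
    member_ids[which.min(rowSums(D))]
  }, character(1))
  names(medoid_ids) <- clusters
  average_paths <- lapply(clusters, function(k) {
    average_route(set$trajectories[ids[labels == k]], M = M)
  })
  names(average_paths) <- clusters
  structure(
    list(labels = labels, clusters = clusters, medoid_ids = medoid_ids,
         average_paths = average_paths, description_mode = mode,
         desc = desc, set = set, rset = rset, measures = measures,
         step_mm = if (!is.null(rset)) attr(rset, "step_mm") else NULL),
    class = "RouteModel"
  )
}

#' @export
print.RouteModel <- function(x, ...) {
  cat(sprintf("<RouteModel [%s]> %d clusters, %d trajectories\n",
              x$description_mode, length(x$clusters), length(x$labels)))
  invisible(x)
}

# Novel path's description-space coordinates under a frozen model.
novel_description <- function(novel, model) {
  if (model$description_mode == "similarity") {
    rs <- resample_equal_arclength(novel, model$step_mm)
    norms <- attr(model$desc, "normalization")
    feats <- lapply(model$measures, function(ms) {
      fun <- switch(ms, dtw = dtw_distance, fastdtw = fastdtw_distance,
                    frechet = frechet_distance)
      d <- vapply(model$rset, function(tr) fun(rs, tr), numeric(1))
      (d - norms[[ms]]$min) / (norms[[ms]]$max - norms[[ms]]$min)
    })
    unlist(feats, use.names = FALSE)
  } else {
    sc <- attr(model$desc, "scaling")
    raw <- flight_characteristics(novel)
    z <- (raw - sc$mean) / ifelse(sc$sd == 0, 1, sc$sd)
    z[sc$sd == 0] <- 0
    unname(z)
  }
}

#' Assign a novel trajectory to an existing route
#'
#' The novel path (for example an agent's simulated flight) is described
#' exactly as the training set was — resampled at the training step and
#' compared to every training trajectory with the same measures and frozen
#' normalization constants, or z-scored with the training means/sds — and
#' assigned to the cluster of the nearest medoid in description space. Ties
#' break deterministically to the lowest cluster index.
#'
#' @param novel a `Trajectory`.
#' @param model a `RouteModel` from [build_route_model()].
#' @return Integer cluster label (named with the medoid id it matched).
#' @export
assign_novel <- function(novel, model) {
  stopifnot(inherits(novel, "Trajectory"), inherits(model, "RouteModel"))
  v <- novel_description(novel, model)
  X <- desc_values(model$desc)
  d2 <- vapply(model$medoid_ids, function(mid) {
    sum((v - X[mid, ])^2)
  }, numeric(1))
  k <- model$clusters[which.min(d2)]   # which.min: first (lowest) on ties
  setNames(as.integer(k), model$medoid_ids[as.character(k)])
}

#' Plot routes: member paths, bold average, faded other averages
#'
#' One panel (PNG file) per cluster plus a combined overview. File names are
#' deterministic: `route_01.png`, ..., `routes_all.png`.
#'
#' @param set the `TrajectorySet`.
#' @param model a `RouteModel`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
plot_routes <- function(set, model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- traj_ids(set)
  all_xy <- do.call(rbind, lapply(set$trajectories, `[[`, "xy"))
  xlim <- range(all_xy[, 1]); ylim <- range(all_xy[, 2])
  cols <- grDevices::hcl.colors(max(2, length(model$clusters)), "Dark 3")
  files <- character(0)
  for (i in seq_along(model$clusters)) {
    k <- model$clusters[i]
    f <- file.path(dir, sprintf("route_%02d.png", i))
    grDevices::png(f, width = 900, height = 300)
    graphics::par(mar = c(4, 4, 2, 1))
    graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "x (mm)",
                   ylab = "y (mm)", main = sprintf("route %d", k))
    for (id in ids[model$labels == k]) {
      graphics::lines(set$trajectories[[id]]$xy, col = grDevices::adjustcolor(cols[i], 0.4))
    }
    for (j in seq_along(model$clusters)) {
      if (j != i) {
        graphics::lines(model$average_paths[[j]],
                        col = grDevices::adjustcolor(cols[j], 0.25), lwd = 3)
      }
    }
    graphics::lines(model$average_paths[[i]], col = cols[i], lwd = 4)
    grDevices::dev.off()
    files <- c(files, f)
  }
  f <- file.path(dir, "routes_all.png")
  grDevices::png(f, width = 900, height = 300)
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "x (mm)",
                 ylab = "y (mm)", main = "all routes")
  for (i in seq_along(model$clusters)) {
    k <- model$clusters[i]
    for (id in ids[model$labels == k]) {
      graphics::lines(set$trajectories[[id]]$xy,
                      col = grDevices::adjustcolor(cols[i], 0.35))
    }
  }
  grDevices::dev.off()
  invisible(c(files, f))
}
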