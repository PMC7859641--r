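#' Seven flight characteristics of one trajectory
#'
#' Summarizes a flight by: mean speed `mean_speed` (mm/s), mean and standard
#' deviation of the lateral position `mean_lateral` / `sd_lateral` (mm), mean
#' and circular standard deviation of the heading `mean_gaze` / `sd_gaze`
#' (radians), the maximal (signed) lateral position `max_lateral` (mm), and
#' the `sinuosity` (traveled distance divided by the straight start-to-end
#' distance, >= 1).
#'
#' Headings are the per-step directions of motion `atan2(dy, dx)` — a proxy
#' for gaze when only positions are tracked — and are averaged circularly
#' (mean resultant direction; circular sd `sqrt(-2 log Rbar)`), since linear
#' statistics break at +/-pi. Standard deviations use the population
#' convention (divide by N). Characteristics are computed on the original,
#' non-resampled trajectory: resampling would destroy speed information.
#'
#' @param traj a `Trajectory` with at least 3 points and distinct start and
#'   end points.
#' @return Named numeric vector of length 7, in the column order of
#'   [characteristics_matrix()].
#' @export
flight_characteristics <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  xy <- traj$xy
  if (nrow(xy) < 3) {
    stop("trajectory '", traj$traj_id,
         "' has fewer than 3 points; heading statistics undefined")
  }
  d <- diff(xy)
  step_len <- sqrt(rowSums(d^2))
  gaps <- diff(traj$frames)
  speeds <- step_len / gaps * traj$frame_rate     # mm/s

  y <- xy[, 2]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

  headings <- atan2(d[, 2], d[, 1])
  C <- mean(cos(headings))
  S <- mean(sin(headings))
  rbar <- min(1, sqrt(C^2 + S^2))
  mean_gaze <- atan2(S, C)
  if (mean_gaze <= -pi) mean_gaze <- pi          # convention: (-pi, pi]
  sd_gaze <- sqrt(-2 * log(max(rbar, .Machine$double.xmin)))

  chord <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  if (chord == 0) {
    stop("trajectory '", traj$traj_id,
         "' starts and ends at the same point; sinuosity undefined ",
         "(division by zero)")
  }
  c(
    mean_speed = mean(speeds),
    mean_lateral = mean(y),
    mean_gaze = mean_gaze,
    sd_lateral = pop_sd(y),
    sd_gaze = sd_gaze,
    max_lateral = max(y),
    sinuosity = sum(step_len) / chord
  )
}

characteristic_names <- c("mean_speed", "mean_lateral", "mean_gaze",
                          "sd_lateral", "sd_gaze", "max_lateral", "sinuosity")

#' Normalized flight-characteristics description matrix
#'
#' One row per trajectory (set order), seven columns (see
#' [flight_characteristics()]), each column z-scored across trajectories
#' using the population standard deviation. A zero-variance column is set to
#' all zeros with a warning.
#'
#' @param set a `TrajectorySet`.
#' @return N x 7 `DescriptionMatrix` (a numeric matrix with attributes
#'   `mode = "characteristics"` and `scaling` recording per-column means and
#'   sds for later novel-trajectory assignment).
#' @export
characteristics_matrix <- function(set) {
  stopifnot(inherits(set, "TrajectorySet"))
  raw <- t(vapply(set$trajectories, flight_characteristics,
                  numeric(length(characteristic_names))))
  rownames(raw) <- traj_ids(set)
  mu <- colMeans(raw)
  sigma <- apply(raw, 2, function(v) sqrt(mean((v - mean(v))^2)))
  z <- raw
  for (j in seq_len(ncol(raw))) {
    if (sigma[j] == 0) {
      warning("characteristic '", colnames(raw)[j],
              "' has zero variance; column set to 0")
      z[, j] <- 0
    } else {
      z[, j] <- (raw[, j] - mu[j]) / sigma[j]
    }
  }
  structure(z, mode_label = "characteristics",
            scaling = list(mean = mu, sd = sigma),
            class = c("DescriptionMatrix", "matrix", "array"))
}

#' @export
print.DescriptionMatrix <- function(x, ...) {
  cat(sprintf("<DescriptionMatrix [%s]> %d trajectories x %d features\n",
              attr(x, "mode_label"), nrow(x), ncol(x)))
  invisible(x)
}

# Strip class/attrs for numeric work.
desc_values <- function(desc) {
  m <- unclass(desc)
  attributes(m) <- list(dim = dim(desc), dimnames = dimnames(desc))
  m
}
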