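#' Pooled median per-frame speed
#'
#' Median of the per-frame displacement magnitudes pooled over every
#' trajectory in the set (not a median of per-trajectory medians). This is
#' the default re-sampling coefficient `s`: resampled paths then advance by
#' roughly one typical frame of travel per point.
#'
#' @param set a `TrajectorySet`.
#' @return Median speed in mm/frame.
#' @export
median_speed <- function(set) {
  stopifnot(inherits(set, "TrajectorySet"), length(set) >= 1)
  steps <- unlist(lapply(set$trajectories, function(tr) {
    d <- diff(tr$xy)
    sqrt(rowSums(d^2)) / diff(tr$frames)
  }))
  median(steps)
}

# Arc-length parameterization helpers -----------------------------------

# Drop repeated positions (zero-length steps) that would degenerate the
# arc-length parameterization.
collapse_repeats <- function(xy) {
  if (nrow(xy) < 2) return(xy)
  d <- diff(xy)
  keep <- c(TRUE, sqrt(rowSums(d^2)) > 0)
  xy[keep, , drop = FALSE]
}

arc_lengths <- function(xy) {
  c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
}

# Place points at the given arc-length positions along the polyline.
interp_at_arclength <- function(xy, s_targets) {
  al <- arc_lengths(xy)
  cbind(
    x = approx(al, xy[, 1], xout = s_targets, ties = "ordered")$y,
    y = approx(al, xy[, 2], xout = s_targets, ties = "ordered")$y
  )
}

#' Resample a trajectory to equal arc-length steps
#'
#' Points are placed at arc-length positions 0, s, 2s, ... along the
#' linearly interpolated polyline; the original endpoint is appended if the
#' total length is not a multiple of `s` (start and end anchor the route, and
#' both similarity measures pin the endpoints). Repeated positions are
#' collapsed first. Speed information is deliberately discarded: resampling
#' exists so the similarity measures compare shapes at a common spatial
#' resolution.
#'
#' @param traj a `Trajectory`.
#' @param step_mm the re-sampling coefficient `s` in mm per resampled step
#'   (default 6).
#' @return An object of class `ResampledTrajectory`: fields `traj_id`, `xy`,
#'   `step_mm`.
#' @export
resample_equal_arclength <- function(traj, step_mm = 6) {
  stopifnot(inherits(traj, "Trajectory"), step_mm > 0)
  xy <- collapse_repeats(traj$xy)
  total <- sum(sqrt(rowSums(diff(xy)^2)))
  if (total < step_mm) {
    stop("trajectory '", traj$traj_id, "' is too short to resample: ",
         "arc length ", signif(total, 4), " mm < step ", step_mm, " mm")
  }
  targets <- seq(0, total, by = step_mm)
  if (targets[length(targets)] < total) targets <- c(targets, total)
  structure(
    list(traj_id = traj$traj_id, xy = interp_at_arclength(xy, targets),
         step_mm = step_mm),
    class = "ResampledTrajectory"
  )
}

#' @export
print.ResampledTrajectory <- function(x, ...) {
  cat(sprintf("<ResampledTrajectory %s> %d points at %g mm/step\n",
              x$traj_id, nrow(x$xy), x$step_mm))
  invisible(x)
}

#' Resample every trajectory of a set
#'
#' @param set a `TrajectorySet`.
#' @param step_mm step in mm, or `NULL` to use the pooled [median_speed()].
#' @return Named list of `ResampledTrajectory`, set order, with the step
#'   used attached as attribute `step_mm`.
#' @export
resample_set <- function(set, step_mm = 6) {
  if (is.null(step_mm)) step_mm <- median_speed(set)
  out <- lapply(set$trajectories, resample_equal_arclength, step_mm = step_mm)
  attr(out, "step_mm") <- step_mm
  out
}

#' Mirror a trajectory about an arena midline
#'
#' Reflects the named coordinate about the midline of the trajectory's (or a
#' supplied arena's) bounding box, optionally reversing point order. Used to
#' make inbound and outbound journeys comparable: an outbound path mirrored
#' (and time-reversed) overlays its inbound twin.
#'
#' @param traj a `Trajectory`.
#' @param axis which coordinate to reflect: `"x"` (along-tunnel) or `"y"`
#'   (lateral).
#' @param reverse_time reverse the point order as well (default FALSE).
#' @param bounds optional numeric length-2 `c(min, max)` of the reflected
#'   coordinate; default is the trajectory's own bounding box.
#' @return A `Trajectory` with id suffixed `_mir<axis>` (and `_rev`).
#' @export
mirror_path <- function(traj, axis = c("y", "x"), reverse_time = FALSE,
                        bounds = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  axis <- match.arg(axis)
  col <- if (axis == "x") 1L else 2L
  v <- traj$xy[, col]
  if (is.null(bounds)) bounds <- range(v)
  mid <- mean(bounds)
  xy <- traj$xy
  xy[, col] <- 2 * mid - v
  frames <- traj$frames
  if (reverse_time) {
    xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  }
  suffix <- paste0("_mir", axis, if (reverse_time) "_rev" else "")
  trajectory(
    traj_id = paste0(traj$traj_id, suffix),
    x = xy[, 1], y = xy[, 2], frames = frames,
    individual_id = traj$individual_id, frame_rate = traj$frame_rate,
    source_dim = traj$source_dim
  )
}
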