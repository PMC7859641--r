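#' Construct a single trajectory
#'
#' A `Trajectory` is one traversal: a time-ordered sequence of planar
#' positions in millimetres plus frame metadata. By convention `x` is the
#' along-tunnel axis and `y` the lateral position, origin at the tunnel
#' entrance corner; the column mapping of input files is configurable via the
#' dialect (see [trajectory_dialect()]).
#'
#' @param traj_id character scalar, unique identifier.
#' @param x,y numeric coordinate vectors in mm, equal length >= 2.
#' @param frames integer-ish frame indices, strictly increasing; defaults to
#'   `seq_along(x) - 1`. May start at any integer.
#' @param individual_id identifier of the animal (optional).
#' @param frame_rate frames per second (default 60).
#' @param source_dim 2 or 3; 3 marks a trajectory that was reduced to its
#'   planar projection on input.
#' @return An object of class `Trajectory` with fields `traj_id`,
#'   `individual_id`, `xy` (n x 2 matrix), `frames`, `frame_rate`,
#'   `source_dim`.
#' @export
trajectory <- function(traj_id, x, y, frames = NULL, individual_id = NA_character_,
                       frame_rate = 60, source_dim = 2) {
  traj_id <- as.character(traj_id)
  if (length(x) != length(y)) {
    stop("x and y must have equal length for trajectory '", traj_id, "'")
  }
  if (length(x) < 2) {
    stop("trajectory '", traj_id, "' needs at least 2 positions")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite coordinates in trajectory '", traj_id, "'")
  }
  if (is.null(frames)) frames <- seq_along(x) - 1
  if (any(diff(frames) <= 0)) {
    stop("frame indices not strictly increasing in trajectory '", traj_id, "'")
  }
  structure(
    list(
      traj_id = traj_id,
      individual_id = as.character(individual_id),
      xy = cbind(x = as.numeric(x), y = as.numeric(y)),
      frames = as.numeric(frames),
      frame_rate = frame_rate,
      source_dim = as.integer(source_dim)
    ),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "<Trajectory %s> %d points, individual %s, %g fps\n",
    x$traj_id, nrow(x$xy), x$individual_id, x$frame_rate
  ))
  invisible(x)
}

#' Bundle trajectories into an ordered set
#'
#' Iteration order is stable (input order); ids must be unique.
#'
#' @param trajectories list of [trajectory()] objects.
#' @return An object of class `TrajectorySet`.
#' @export
trajectory_set <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  ok <- vapply(trajectories, inherits, logical(1), "Trajectory")
  if (!all(ok)) stop("all elements must be Trajectory objects")
  ids <- unname(vapply(trajectories, `[[`, character(1), "traj_id"))
  if (anyDuplicated(ids)) {
    stop("duplicate traj_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(trajectories) <- ids
  structure(list(trajectories = trajectories, ids = ids),
            class = "TrajectorySet")
}

#' @export
length.TrajectorySet <- function(x) length(x$trajectories)

#' @export
`[[.TrajectorySet` <- function(x, i) x$trajectories[[i]]

#' @export
print.TrajectorySet <- function(x, ...) {
  n_ind <- length(unique(vapply(x$trajectories, `[[`, character(1),
                                "individual_id")))
  cat(sprintf("<TrajectorySet> %d trajectories, %d individuals\n",
              length(x), n_ind))
  invisible(x)
}

traj_ids <- function(set) set$ids

#' Column-mapping dialect for trajectory tables
#'
#' Describes how a delimited-text trajectory table maps onto the fields the
#' package needs. Defaults match the CSVs this package writes. A YAML file
#' with any subset of these keys can be loaded with [read_dialect()].
#'
#' @param sep field separator (default ",").
#' @param traj_id,frame,x,y,z,individual_id column names in the file header;
#'   `z` and `individual_id` are optional columns.
#' @param frame_rate recording rate in frames per second (default 60).
#' @return Named list of class `trajectory_dialect`.
#' @export
trajectory_dialect <- function(sep = ",", traj_id = "traj_id", frame = "frame",
                               x = "x", y = "y", z = "z",
                               individual_id = "individual_id",
                               frame_rate = 60) {
  structure(
    list(sep = sep, traj_id = traj_id, frame = frame, x = x, y = y, z = z,
         individual_id = individual_id, frame_rate = frame_rate),
    class = "trajectory_dialect"
  )
}

#' Load a dialect from a YAML file
#'
#' @param path YAML file; keys as in [trajectory_dialect()], missing keys keep
#'   their defaults.
#' @return A `trajectory_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- trajectory_dialect()
  known <- intersect(names(cfg), names(base))
  base[known] <- cfg[known]
  base
}

#' Read trajectories from a delimited-text file
#'
#' One `Trajectory` per distinct id, rows sorted by frame within id. A `z`
#' column, if present, is dropped: recording arenas that are invariant along
#' altitude justify reducing tracks to their planar projection. Ids with
#' fewer than 2 rows are skipped with a warning; duplicated frame indices
#' within an id are a validation error.
#'
#' @param path delimited-text file with a header row.
#' @param dialect a [trajectory_dialect()] (or YAML path understood by
#'   [read_dialect()]).
#' @return A `TrajectorySet` in first-appearance file order.
#' @export
read_trajectories <- function(path, dialect = trajectory_dialect()) {
  if (is.character(dialect)) dialect <- read_dialect(dialect)
  df <- read.table(path, header = TRUE, sep = dialect$sep,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("traj_id", "frame", "x", "y")) {
    if (!dialect[[col]] %in% names(df)) {
      stop("missing required column '", dialect[[col]], "' in ", path)
    }
  }
  has_z <- dialect$z %in% names(df)
  has_ind <- dialect$individual_id %in% names(df)
  ids <- unique(as.character(df[[dialect$traj_id]]))
  trajs <- list()
  for (id in ids) {
    rows <- df[as.character(df[[dialect$traj_id]]) == id, , drop = FALSE]
    if (nrow(rows) < 2) {
      warning("trajectory '", id, "' has fewer than 2 rows; skipped")
      next
    }
    ord <- order(rows[[dialect$frame]])
    rows <- rows[ord, , drop = FALSE]
    if (anyDuplicated(rows[[dialect$frame]])) {
      stop("duplicated frame index in trajectory '", id, "'")
    }
    trajs[[id]] <- trajectory(
      traj_id = id,
      x = rows[[dialect$x]],
      y = rows[[dialect$y]],
      frames = rows[[dialect$frame]],
      individual_id = if (has_ind) rows[[dialect$individual_id]][1] else NA_character_,
      frame_rate = dialect$frame_rate,
      source_dim = if (has_z) 3L else 2L
    )
  }
  if (length(trajs) == 0) stop("no usable trajectories in ", path)
  trajectory_set(trajs)
}

#' Write a trajectory set to CSV
#'
#' Long format, one row per observation, using the dialect's column names.
#'
#' @param set a `TrajectorySet`.
#' @param path output file.
#' @param dialect column naming; see [trajectory_dialect()].
#' @export
write_trajectories <- function(set, path, dialect = trajectory_dialect()) {
  stopifnot(inherits(set, "TrajectorySet"))
  rows <- lapply(set$trajectories, function(tr) {
    data.frame(
      traj_id = tr$traj_id, individual_id = tr$individual_id,
      frame = tr$frames, x = tr$xy[, 1], y = tr$xy[, 2],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out) <- c(dialect$traj_id, dialect$individual_id, dialect$frame,
                  dialect$x, dialect$y)
  write.table(out, path, sep = dialect$sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cluster labels to CSV
#'
#' @param set a `TrajectorySet`; every trajectory must be labeled.
#' @param labels named integer vector, `traj_id -> cluster`.
#' @param path output CSV (columns traj_id, individual_id, cluster).
#' @export
write_labels <- function(set, labels, path) {
  stopifnot(inherits(set, "TrajectorySet"))
  missing_ids <- setdiff(traj_ids(set), names(labels))
  if (length(missing_ids) > 0) {
    stop("unlabeled trajectory id(s): ", paste(missing_ids, collapse = ", "))
  }
  out <- data.frame(
    traj_id = traj_ids(set),
    individual_id = vapply(set$trajectories, `[[`, character(1),
                           "individual_id"),
    cluster = as.integer(labels[traj_ids(set)]),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cluster labels written by [write_labels()]
#'
#' @param path CSV with columns traj_id and cluster.
#' @return Named integer vector, `traj_id -> cluster`.
#' @export
read_labels <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  setNames(as.integer(df$cluster), as.character(df$traj_id))
}
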