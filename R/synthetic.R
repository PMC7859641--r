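#' Default planted routes for the synthetic tunnel
#'
#' Four corridors through a 1400 x 300 mm tunnel, all sharing the entrance
#' (0, 150) and exit (1400, 150): one hugging each wall, and two crossing
#' between walls in opposite directions. Corridor centerlines are separated
#' laterally by about 180 mm over most of the tunnel — far more than the
#' default meander noise — emulating distinct paths between clutter objects.
#'
#' @param arena numeric `c(length_mm, width_mm)`.
#' @return List of waypoint matrices (columns x, y).
#' @export
default_routes <- function(arena = c(1400, 300)) {
  L <- arena[1]; W <- arena[2]
  xs <- seq(0, L, length.out = 8)
  mid <- W / 2
  lo <- 0.2 * W   # wall-hugging lanes
  hi <- 0.8 * W
  mk <- function(ys) cbind(x = xs, y = ys)
  list(
    low    = mk(c(mid, lo, lo, lo, lo, lo, lo, mid)),
    high   = mk(c(mid, hi, hi, hi, hi, hi, hi, mid)),
    rising = mk(c(mid, lo, lo, mid, hi, hi, hi, mid)),
    falling = mk(c(mid, hi, hi, mid, lo, lo, lo, mid))
  )
}

#' Configuration of the synthetic planted-route generator
#'
#' The generator emulates flights through a cluttered tunnel: each path
#' follows its route's waypoints (jittered per path), traverses the tunnel
#' with per-frame speeds drawn around `speed_mean`, and meanders laterally
#' with an AR(1) noise process (independent per-frame noise would be
#' unrealistically jagged). Defaults mirror the recorded-bee setting: a
#' 1400 x 300 mm tunnel, 60 frames/s, typical speed 6 mm/frame.
#'
#' @param arena `c(length_mm, width_mm)` (default `c(1400, 300)`).
#' @param routes list of waypoint matrices (default [default_routes()]).
#' @param paths_per_route paths generated per route (default 20).
#' @param lateral_noise_sd stationary sd of the AR(1) lateral meander in mm
#'   (default 8).
#' @param noise_ar AR(1) coefficient of the meander (default 0.95).
#' @param waypoint_jitter_sd per-path waypoint jitter sd in mm (default 10).
#' @param speed_mean,speed_sd per-frame speed draw in mm/frame (defaults 6
#'   and 1.5).
#' @param frame_rate frames per second (default 60).
#' @param seed integer seed.
#' @return Named list of class `synthetic_config`.
#' @export
synthetic_config <- function(arena = c(1400, 300), routes = default_routes(arena),
                             paths_per_route = 20, lateral_noise_sd = 8,
                             noise_ar = 0.95, waypoint_jitter_sd = 10,
                             speed_mean = 6, speed_sd = 1.5, frame_rate = 60,
                             seed = 1) {
  stopifnot(length(arena) == 2, all(arena > 0), paths_per_route >= 1,
            lateral_noise_sd >= 0, waypoint_jitter_sd >= 0,
            noise_ar >= 0, noise_ar < 1, speed_mean > 0, speed_sd >= 0)
  for (r in routes) {
    if (nrow(r) < 2) stop("degenerate route: needs at least 2 waypoints")
    if (any(r[, 1] < 0 | r[, 1] > arena[1] | r[, 2] < 0 | r[, 2] > arena[2])) {
      stop("route waypoints must lie within the arena")
    }
  }
  structure(
    list(arena = arena, routes = routes, paths_per_route = paths_per_route,
         lateral_noise_sd = lateral_noise_sd, noise_ar = noise_ar,
         waypoint_jitter_sd = waypoint_jitter_sd, speed_mean = speed_mean,
         speed_sd = speed_sd, frame_rate = frame_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# One path along a jittered route centerline.
simulate_path <- function(waypoints, cfg) {
  L <- cfg$arena[1]; W <- cfg$arena[2]
  n_wp <- nrow(waypoints)
  wp <- waypoints
  if (cfg$waypoint_jitter_sd > 0) {
    wp <- wp + matrix(rnorm(2 * n_wp, sd = cfg$waypoint_jitter_sd), n_wp)
    wp[, 1] <- pmin(pmax(wp[, 1], 0), L)
    wp[, 2] <- pmin(pmax(wp[, 2], 0), W)
  }
  # smooth centerline: x linear in the waypoint parameter (keeps monotone
  # routes monotone), y a natural cubic spline
  tt <- seq_len(n_wp)
  td <- seq(1, n_wp, length.out = 40 * (n_wp - 1))
  cx <- approx(tt, wp[, 1], xout = td)$y
  cy <- spline(tt, wp[, 2], xout = td)$y
  center <- cbind(cx, pmin(pmax(cy, 0), W))
  al <- arc_lengths(center)
  total <- al[length(al)]
  # traverse with random per-frame speeds until the end is reached
  pos <- 0
  positions <- numeric(0)
  while (pos < total) {
    positions <- c(positions, pos)
    pos <- pos + max(0.5, rnorm(1, cfg$speed_mean, cfg$speed_sd))
  }
  positions <- c(positions, total)
  xy <- interp_at_arclength(center, positions)
  n <- nrow(xy)
  if (cfg$lateral_noise_sd > 0 && n > 1) {
    e <- numeric(n)
    innov_sd <- cfg$lateral_noise_sd * sqrt(1 - cfg$noise_ar^2)
    e[1] <- rnorm(1, 0, cfg$lateral_noise_sd)
    for (i in 2:n) e[i] <- cfg$noise_ar * e[i - 1] + rnorm(1, 0, innov_sd)
    xy[, 2] <- pmin(pmax(xy[, 2] + e, 0), W)
  }
  xy
}

#' Generate a planted-route trajectory dataset
#'
#' Fully reproducible under `cfg$seed`. Paths differ in length (speed draws
#' and jitter), stay inside the arena, and are labeled with their generating
#' route.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `set` (a `TrajectorySet`), `labels` (named integer
#'   vector, `traj_id -> planted route`), and `cfg`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    trajs <- list()
    labels <- integer(0)
    for (r in seq_along(cfg$routes)) {
      for (p in seq_len(cfg$paths_per_route)) {
        xy <- simulate_path(cfg$routes[[r]], cfg)
        id <- sprintf("r%dp%02d", r, p)
        # ~3 paths per synthetic individual, echoing repeated recordings
        ind <- sprintf("r%di%02d", r, (p - 1) %/% 3 + 1)
        trajs[[id]] <- trajectory(id, xy[, 1], xy[, 2],
                                  individual_id = ind,
                                  frame_rate = cfg$frame_rate)
        labels[id] <- r
      }
    }
    list(set = trajectory_set(trajs), labels = labels, cfg = cfg)
  })
}

#' Canonical planted-route benchmark
#'
#' Four routes through a 1400 x 300 mm tunnel, 20 paths each (80
#' trajectories — the scale of a real recorded dataset), generated with the
#' documented seed 2021. Every default of [synthetic_config()] applies.
#'
#' @param seed generator seed (default 2021, the documented benchmark seed).
#' @return As [generate_dataset()].
#' @export
default_benchmark <- function(seed = 2021) {
  generate_dataset(synthetic_config(seed = seed))
}
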