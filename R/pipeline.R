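#' Default pipeline configuration
#'
#' @param input trajectory CSV path, or `NULL` to simulate the planted-route
#'   benchmark.
#' @param out_dir output directory for all artifacts.
#' @param mode `"similarity"` or `"characteristics"` description.
#' @param measures similarity measures (similarity mode).
#' @param step_mm resampling coefficient; `NULL` = pooled median speed.
#' @param seed global seed; every stage derives its own seed from it
#'   (`stage seed = global + 1009 * weighted character sum of the stage
#'   name, mod 2^31`), so changing one stage's settings never perturbs
#'   another's draws.
#' @param m3c list of overrides for [m3c_config()].
#' @param robustness `NULL`, or a list with `steps` (and optionally
#'   `n_null_sims`) to run [resampling_sweep()].
#' @param synthetic list of overrides for [synthetic_config()] when no input
#'   file is given.
#' @param dialect input column mapping (see [trajectory_dialect()]).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(input = NULL, out_dir = "routeclust_run",
                       mode = c("similarity", "characteristics"),
                       measures = c("dtw", "frechet"), step_mm = 6,
                       seed = 1, m3c = list(), robustness = NULL,
                       synthetic = list(), dialect = trajectory_dialect()) {
  mode <- match.arg(mode)
  structure(
    list(input = input, out_dir = out_dir, mode = mode, measures = measures,
         step_mm = step_mm, seed = as.integer(seed), m3c = m3c,
         robustness = robustness, synthetic = synthetic, dialect = dialect),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Any subset of the [run_config()] arguments may appear as top-level keys.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- intersect(names(cfg), names(formals(run_config)))
  do.call(run_config, cfg[known])
}

#' Run the full route-discovery pipeline
#'
#' simulate/read -> resample -> describe -> consensus-cluster -> embed ->
#' route model -> (optional) robustness sweep. All tables are CSV, figures
#' PNG; `manifest.json` records the configuration and artifact list. Fully
#' deterministic under the global seed.
#'
#' @param cfg a [run_config()] (or YAML path).
#' @return Invisibly, a list with the main in-memory results (`set`, `desc`,
#'   `m3c`, `model`, `embedding`, optionally `robustness`) and `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, basename(path)); path }

  # -- input
  if (is.null(cfg$input)) {
    scfg <- do.call(synthetic_config,
                    c(cfg$synthetic,
                      list(seed = stage_seed(cfg$seed, "simulate"))))
    sim <- generate_dataset(scfg)
    set <- sim$set
    write_trajectories(set, keep(file.path(cfg$out_dir, "trajectories.csv")))
    write_labels(set, sim$labels,
                 keep(file.path(cfg$out_dir, "true_labels.csv")))
  } else {
    set <- read_trajectories(cfg$input, cfg$dialect)
  }

  # -- describe
  if (cfg$mode == "similarity") {
    rset <- resample_set(set, cfg$step_mm)
    mats <- lapply(cfg$measures, function(ms) pairwise_distance_matrix(rset, ms))
    for (i in seq_along(mats)) {
      write.table(
        cbind(traj_id = rownames(mats[[i]]), as.data.frame(desc_values(mats[[i]]))),
        keep(file.path(cfg$out_dir, paste0("dist_", cfg$measures[i], ".csv"))),
        sep = ",", row.names = FALSE, quote = FALSE)
    }
    desc <- similarity_description(mats)
  } else {
    rset <- NULL
    desc <- characteristics_matrix(set)
  }
  write.table(
    cbind(traj_id = rownames(desc), as.data.frame(desc_values(desc))),
    keep(file.path(cfg$out_dir, "description.csv")),
    sep = ",", row.names = FALSE, quote = FALSE)

  # -- cluster
  mcfg <- do.call(m3c_config, c(cfg$m3c,
                                list(seed = stage_seed(cfg$seed, "cluster"))))
  m3c <- m3c_select_k(desc, mcfg)
  write.table(m3c$summary, keep(file.path(cfg$out_dir, "pac_table.csv")),
              sep = ",", row.names = FALSE, quote = FALSE)
  for (K in mcfg$K_range) {
    write_labels(set, m3c$per_K[[paste0("K", K)]]$labels,
                 keep(file.path(cfg$out_dir, sprintf("labels_K%02d.csv", K))))
  }

  # -- visualize / model at the preferred candidate (smallest-PAC candidate,
  # falling back to the global PAC minimum); all candidates stay reported
  cand <- m3c$candidates
  Ksel <- if (length(cand) > 0) {
    cand[which.min(m3c$summary$pac[match(cand, m3c$summary$K)])]
  } else {
    m3c$summary$K[which.min(m3c$summary$pac)]
  }
  labels <- m3c$per_K[[paste0("K", Ksel)]]$labels
  emb <- embed_tsne(desc, seed = stage_seed(cfg$seed, "tsne"))
  write.table(
    data.frame(traj_id = rownames(emb), emb, cluster = labels[rownames(emb)]),
    keep(file.path(cfg$out_dir, "tsne_embedding.csv")),
    sep = ",", row.names = FALSE, quote = FALSE)
  model <- build_route_model(set, labels, desc, rset = rset,
                             measures = if (cfg$mode == "similarity") cfg$measures)
  plot_routes(set, model, file.path(cfg$out_dir, "figures"))
  artifacts <- c(artifacts, "figures/")

  # -- robustness (optional)
  robustness <- NULL
  if (!is.null(cfg$robustness)) {
    steps <- cfg$robustness$steps %||% 2:11
    nn <- cfg$robustness$n_null_sims %||% 100
    rcfg <- do.call(m3c_config, c(cfg$m3c,
                                  list(seed = stage_seed(cfg$seed, "robustness"))))
    robustness <- resampling_sweep(set, steps = steps,
                                   reference_step = cfg$step_mm %||% 6,
                                   cfg = rcfg, measures = cfg$measures,
                                   n_null_sims = nn)
    write.table(robustness$table,
                keep(file.path(cfg$out_dir, "robustness.csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("routeclust")),
    seed = cfg$seed, mode = cfg$mode, measures = cfg$measures,
    step_mm = cfg$step_mm, selected_K = Ksel,
    candidates = as.integer(cand), artifacts = sort(unique(artifacts))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(set = set, desc = desc, m3c = m3c, model = model,
                 embedding = emb, robustness = robustness,
                 selected_K = Ksel, out_dir = cfg$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
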