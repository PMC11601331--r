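#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages `synth` (olfactory-bulb patterns and a synthetic
#' odor session), `simulate` (optional spiking-network experiment),
#' `manifolds`, `distances`, `capacity` and `stats` in dependency order,
#' writing CSV/JSON outputs and a run manifest (config snapshot, seeds,
#' per-stage wall time, content hashes of every output file).  Rerunning
#' with the same configuration and seed reproduces the hashes of all
#' deterministic stages.
#'
#' @param config a named list (or path to a JSON file) with entries
#'   `seed` (integer), `out_dir` (output directory), optional `stages`
#'   (character subset of the stage names), `resume` (skip stages whose
#'   outputs exist), and per-stage parameter lists `synth`, `simulate`,
#'   `manifolds`, `distances`, `capacity` (see Details in the vignette).
#' @return the manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  required <- c("seed", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("configuration is missing required key(s): ",
         paste(missing, collapse = ", "))
  all_stages <- c("synth", "simulate", "manifolds", "distances",
                  "capacity", "stats")
  stages <- if (is.null(config$stages)) setdiff(all_stages, "simulate") else
    config$stages
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop("unknown stage(s) in configuration: ", paste(bad, collapse = ", "))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  resume <- isTRUE(config$resume)
  manifest <- list(config = config, seed = seed, stages = list(),
                   package_version = as.character(
                     utils::packageVersion("pdpmanifold")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  outputs <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, produces, fn) {
    paths <- file.path(out_dir, produces)
    if (resume && all(file.exists(paths)) && !(name %in% stages)) return()
    if (!(name %in% stages)) return()
    t0 <- proc.time()[["elapsed"]]
    set.seed(seed + match(name, all_stages))
    fn(paths)
    manifest$stages[[name]] <<- list(
      seed = seed + match(name, all_stages),
      wall_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = produces)
    outputs <<- c(outputs, paths)
  }

  syn_cfg <- config$synth
  run_stage("synth", c("ob_patterns.csv", "ob_achieved_correlation.csv",
                       "synth_session.csv"), function(paths) {
    panel <- default_odor_panel(
      r_within = syn_cfg$r_within %||% 0.5)
    pat <- make_ob_patterns(panel,
                            n_mitral = syn_cfg$n_mitral %||% 1500)
    write.csv(pat$rates, paths[1], row.names = FALSE)
    write.csv(pat$achieved_correlation, paths[2])
    arr <- synthetic_odor_session(
      n_neurons = syn_cfg$n_neurons %||% 120,
      n_odors = syn_cfg$n_odors %||% 2,
      n_trials = syn_cfg$n_trials %||% 3)
    flat <- as.data.frame.table(arr, responseName = "rate")
    names(flat) <- c("neuron", "bin", "trial", "odor", "rate")
    write.csv(flat, paths[3], row.names = FALSE)
    state$arr <- arr
    state$panel <- panel
    state$patterns <- pat
  })

  sim_cfg <- config$simulate
  run_stage("simulate", "experiment_rates.csv", function(paths) {
    exp <- run_experiment(
      setting = sim_cfg$setting %||% "A",
      assemblies = sim_cfg$assemblies %||% c("A1", "A2"),
      n_trials = sim_cfg$n_trials %||% 2,
      n_instantiations = sim_cfg$n_instantiations %||% 1,
      seed = seed)
    arr <- exp$instantiations[[1]]$rates$none
    flat <- as.data.frame.table(arr, responseName = "rate")
    names(flat) <- c("neuron", "bin", "trial", "odor", "rate")
    write.csv(flat, paths[1], row.names = FALSE)
    state$experiment <- exp
  })

  run_stage("manifolds", "manifold_points.csv", function(paths) {
    if (is.null(state$arr)) stop("stage 'manifolds' needs the output of ",
                                 "stage 'synth'")
    mans <- build_manifolds(state$arr,
                            window = config$manifolds$window %||% c(1, 4))
    state$manifolds <- mans
    flat <- do.call(rbind, lapply(mans, function(m) {
      data.frame(odor = m$label, point = seq_len(nrow(m$points)),
                 m$points, check.names = FALSE)
    }))
    write.csv(flat, paths[1], row.names = FALSE)
  })

  dist_cfg <- config$distances
  run_stage("distances", c("distances_dE.csv", "distances_dM.csv",
                           "distances_meta.json"), function(paths) {
    if (is.null(state$manifolds)) stop("stage 'distances' needs the ",
                                       "output of stage 'manifolds'")
    d <- distance_matrices(state$manifolds,
                           n_neurons_sub = dist_cfg$n_neurons_sub %||% 70,
                           n_repeats = dist_cfg$n_repeats %||% 10,
                           seed = seed + 10L)
    state$distances <- d
    write_distances(d, out_dir, "distances")
  })

  cap_cfg <- config$capacity
  run_stage("capacity", "capacity.csv", function(paths) {
    if (is.null(state$manifolds)) stop("stage 'capacity' needs the ",
                                       "output of stage 'manifolds'")
    N <- ncol(state$manifolds[[1]]$points)
    nsub <- cap_cfg$n_neurons_sub %||% N
    # keep the pooled point count below the subspace dimension so every
    # dichotomy of the subsample is linearly separable
    psub <- cap_cfg$n_points_sub %||%
      min(nrow(state$manifolds[[1]]$points), floor(nsub / 2))
    cfg <- capacity_config(
      n_neurons_sub = nsub,
      n_points_sub = psub,
      n_repeats = cap_cfg$n_repeats %||% 5,
      n_gaussian_samples = cap_cfg$n_gaussian_samples %||% 50,
      seed = seed + 20L)
    fit <- manifold_capacity(state$manifolds[[1]], state$manifolds[[2]],
                             config = cfg)
    state$capacity <- fit
    df <- data.frame(pair = paste(fit$labels, collapse = ":"),
                     alpha = fit$alpha, t(fit$measures),
                     shuffle_alpha = fit$shuffle_alpha,
                     n_repeats = cfg$n_repeats, seed = cfg$seed)
    write.csv(df, paths[1], row.names = FALSE)
  })

  run_stage("stats", "stats_summary.csv", function(paths) {
    if (is.null(state$capacity)) stop("stage 'stats' needs the output of ",
                                      "stage 'capacity'")
    pr <- state$capacity$per_repeat
    mw <- mann_whitney(pr$alpha, pr$shuffle_alpha)
    df <- as.data.frame(mw)
    df$signif <- significance_label(df$p_adj)
    write.csv(df, paths[1], row.names = FALSE)
  })

  manifest$hashes <- as.list(tools::md5sum(outputs))
  names(manifest$hashes) <- basename(outputs)
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
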