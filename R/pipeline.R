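default_config <- function() {
  list(
    stages = c("simulate", "dfnc", "states", "stats", "classify"),
    manifest = NULL,
    out_dir = "dynconn-out",
    seed = 1L,
    simulate = list(n_per_group = c(HC = 10L, NS = 10L, SI = 10L, SA = 10L),
                    C = 23L, T = 230L, TR = 2, K = 6L, noise_sd = 1),
    dfnc = list(window_length = 50L, step = 1L, taper = "rectangular",
                taper_sigma = 3, lambda = 0.1,
                lambda_grid = c(0.01, 0.03, 0.1, 0.3), cv_folds = 3L,
                n_lambda_windows = 10L),
    states = list(k = NULL, k_range = 2:10, n_replicates = 50L),
    stats = list(alpha = 0.05, var_equal = TRUE, pairs = NULL),
    classify = list(kernel = "rbf", C_grid = 2^seq(-5, 5, by = 2),
                    gamma_grid = 2^seq(-5, 5, by = 2), N_grid = c(1, 2, 5, 10),
                    n_permutations = 0L, leakage_mode = "nested",
                    permutation_mode = "full", pairs = NULL)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a config as a named list or a YAML file path, injects defaults for
#' every missing field, runs cross-field checks, and either returns the
#' normalized config or raises one error aggregating every problem found.
#'
#' @param config Named list or path to a YAML file.
#' @return The normalized config (list of class `run_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s",
                                            config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML path")
  def <- default_config()
  merged <- utils::modifyList(def, config)
  errors <- character(0)
  bad_stage <- setdiff(merged$stages, def$stages)
  if (length(bad_stage) > 0) {
    errors <- c(errors, paste("unknown stage(s):",
                              paste(bad_stage, collapse = ", ")))
  }
  if (is.null(merged$seed)) {
    merged$seed <- 1L
    inform("no seed in config; deterministic default seed 1 injected")
  }
  if (!is.null(merged$manifest) && !file.exists(merged$manifest)) {
    errors <- c(errors, sprintf("manifest path does not exist: %s",
                                merged$manifest))
  }
  if (is.null(merged$manifest) && !"simulate" %in% merged$stages) {
    errors <- c(errors, "no manifest given and the simulate stage is off")
  }
  Tn <- merged$simulate$T
  if (!is.null(Tn) && merged$dfnc$window_length > Tn) {
    errors <- c(errors, sprintf(
      "window_length (%d) must not exceed T (%d)",
      merged$dfnc$window_length, Tn))
  }
  if (length(merged$classify$C_grid) == 0 ||
      length(merged$classify$gamma_grid) == 0) {
    errors <- c(errors, "classifier grids must be nonempty")
  }
  if (!is.null(merged$states$k) && merged$states$k < 1) {
    errors <- c(errors, "states$k must be >= 1")
  }
  if (length(errors) > 0) {
    abort(paste0("invalid config:\n", paste("-", errors, collapse = "\n")))
  }
  structure(merged, class = "run_config")
}

#' Run the dFNC pipeline end to end (or selected stages)
#'
#' Executes the configured stages in dependency order — simulate (or load a
#' manifest), windowed dFNC estimation, state clustering and dynamics,
#' edgewise and metric group statistics, per-state classification — and
#' writes every table to `out_dir` as tab-separated text together with a
#' provenance sidecar (config, seed, package version). Reruns with an
#' identical config are identical.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param fnc Optional precomputed named list of `windowed_fnc` (from
#'   [cohort_dfnc()]): lets the states stage run without re-running the
#'   dfnc stage.
#' @return List of class `pipeline_result`: `manifest`, `fnc`, `model`,
#'   `dynamics`, `membership`, `stats`, `metric_stats`, `classification`,
#'   `config` (stages that did not run are `NULL`).
#' @export
run_pipeline <- function(config = list(), fnc = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg, fnc = fnc)
  stage_on <- function(s) s %in% cfg$stages

  if (stage_on("simulate")) {
    sim <- cfg$simulate
    design <- suicidality_design(
      n_per_group = unlist(sim$n_per_group), C = sim$C, T = sim$T,
      TR = sim$TR, K = sim$K, noise_sd = sim$noise_sd,
      seed = derive_seed(cfg$seed, 1L)
    )
    cohort <- simulate_cohort(design, dir = file.path(cfg$out_dir, "cohort"))
    res$manifest <- cohort$manifest
    tcs <- cohort$time_courses
    res$ground_truth <- cohort$ground_truth
  } else {
    res$manifest <- read_manifest(cfg$manifest)
    tcs <- read_time_courses(res$manifest)
  }

  if (stage_on("dfnc")) {
    params <- dfnc_params(
      window_length = cfg$dfnc$window_length, step = cfg$dfnc$step,
      taper = cfg$dfnc$taper, taper_sigma = cfg$dfnc$taper_sigma,
      lambda = cfg$dfnc$lambda, lambda_grid = cfg$dfnc$lambda_grid,
      cv_folds = cfg$dfnc$cv_folds,
      n_lambda_windows = cfg$dfnc$n_lambda_windows,
      seed = derive_seed(cfg$seed, 2L)
    )
    res$fnc <- cohort_dfnc(tcs, params)
  }

  if (stage_on("states")) {
    if (is.null(res$fnc)) abort("states stage needs the dfnc stage output")
    if (is.null(cfg$states$k)) {
      sel <- select_k_elbow(res$fnc, k_range = cfg$states$k_range,
                            n_replicates = max(5L,
                                               cfg$states$n_replicates %/% 4L),
                            seed = derive_seed(cfg$seed, 3L))
      k <- sel$k
      res$k_selection <- sel
    } else {
      k <- cfg$states$k
    }
    res$model <- kmeans_states(res$fnc, k,
                               n_replicates = cfg$states$n_replicates,
                               seed = derive_seed(cfg$seed, 4L))
    res$dynamics <- cohort_dynamics(res$model, res$manifest)
    res$membership <- state_membership_table(res$model, res$manifest)
    res$state_fnc <- cohort_state_fnc(res$model, res$fnc, res$manifest)
    write_tsv_quiet(res$dynamics, file.path(cfg$out_dir, "dynamics.tsv"))
    write_tsv_quiet(res$membership, file.path(cfg$out_dir, "membership.tsv"))
    for (s in seq_len(res$model$k)) {
      write_tsv_quiet(as.data.frame(res$model$centroid_matrices[[s]]),
                      file.path(cfg$out_dir,
                                sprintf("centroid_state%d.tsv", s)))
    }
  }

  groups <- unique(res$manifest$group)
  all_pairs <- if (length(groups) >= 2) {
    asplit(utils::combn(sort(groups), 2), 2)
  } else {
    list()
  }

  if (stage_on("stats")) {
    if (is.null(res$state_fnc)) abort("stats stage needs the states stage")
    pairs <- cfg$stats$pairs %||% all_pairs
    res$stats <- purrr::map_dfr(pairs, function(pr) {
      compare_state_fnc(res$state_fnc, pr, alpha = cfg$stats$alpha,
                        var_equal = cfg$stats$var_equal)
    })
    res$metric_stats <- purrr::map_dfr(pairs, function(pr) {
      metrics_tests(res$dynamics, pr, alpha = cfg$stats$alpha,
                    var_equal = cfg$stats$var_equal)
    })
    write_tsv_quiet(res$stats, file.path(cfg$out_dir, "edgewise_stats.tsv"))
    write_tsv_quiet(res$metric_stats,
                    file.path(cfg$out_dir, "metric_stats.tsv"))
  }

  if (stage_on("classify")) {
    if (is.null(res$state_fnc)) abort("classify stage needs the states stage")
    cl <- cfg$classify
    ccfg <- classifier_config(
      kernel = cl$kernel, C_grid = cl$C_grid, gamma_grid = cl$gamma_grid,
      N_grid = cl$N_grid, n_permutations = cl$n_permutations,
      leakage_mode = cl$leakage_mode, permutation_mode = cl$permutation_mode,
      seed = derive_seed(cfg$seed, 5L)
    )
    pairs <- cl$pairs %||% all_pairs
    res$classification <- classify_all_states(res$state_fnc, pairs,
                                              config = ccfg)
    write_tsv_quiet(res$classification,
                    file.path(cfg$out_dir, "classification.tsv"))
  }

  sidecar <- list(
    seed = cfg$seed,
    stages = cfg$stages,
    config_hash = rlang::hash(unclass(cfg)),
    package_version = as.character(utils::packageVersion("dynconn"))
  )
  yaml::write_yaml(sidecar, file.path(cfg$out_dir, "provenance.yaml"))
  structure(res, class = "pipeline_result")
}

write_tsv_quiet <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
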