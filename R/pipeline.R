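#' Load a pipeline configuration
#'
#' One YAML file drives the whole pipeline; missing blocks fall back to
#' package defaults, and a `seed` at the top level propagates to every
#' stochastic stage.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides Named list of scalar overrides (e.g. `list(seed = 7)`).
#' @return A `herbrx_pipeline_config` list with blocks `generator`,
#'   `cluster`, `reward`, `termination`, `agents`, `recommender`, `outdir`,
#'   `seed`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  seed <- as.integer(raw$seed %||% 1L)
  cfg <- list(
    seed = seed,
    outdir = raw$outdir %||% "herbrx-output",
    generator = do.call(generator_config,
                        utils::modifyList(list(seed = seed),
                                          raw$generator %||% list())),
    cluster = utils::modifyList(
      list(k_grid = c(3L, 5L, 8L), representative_k = NULL), raw$cluster %||% list()),
    reward = do.call(reward_config, raw$reward %||% list()),
    termination = do.call(termination_config, raw$termination %||% list()),
    agents = utils::modifyList(
      list(kinds = c("dqn", "drqn"),
           hidden_dqn = c(400L, 300L), hidden_drqn = c(300L, 512L),
           recurrent_size = 512L,
           train = list()),
      raw$agents %||% list()),
    recommender = utils::modifyList(
      list(thresholds = c(0.1, 0.2, 0.3, 0.4), hidden_sizes = c(256L, 128L),
           epochs = 60L),
      raw$recommender %||% list()),
    train_fraction = raw$train_fraction %||% 0.8)
  class(cfg) <- "herbrx_pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.manifest <- function(outdir, stage, cfg, counts) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  man <- list(stage = stage, seed = cfg$seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              counts = counts)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA),
             file.path(outdir, paste0("manifest-", stage, ".json")),
             useBytes = TRUE)
}

#' Pipeline stage: simulate a synthetic cohort
#' @param cfg A [pipeline_config()].
#' @return Paths of the written cohort and ground-truth files (invisibly);
#'   side effect: files under `cfg$outdir`.
#' @export
pipeline_simulate <- function(cfg) {
  gen <- generate_cohort(cfg$generator)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(cfg$outdir, "cohort.jsonl")
  write_cohort(gen$cohort, cohort_path, "jsonl")
  write_vocabulary(gen$cohort$symptom_vocab,
                   file.path(cfg$outdir, "symptom_vocab.txt"))
  write_vocabulary(gen$cohort$herb_vocab,
                   file.path(cfg$outdir, "herb_vocab.txt"))
  truth_path <- file.path(cfg$outdir, "ground_truth.jsonl")
  write_ground_truth(gen, truth_path)
  .manifest(cfg$outdir, "simulate", cfg,
            list(patients = length(gen$cohort$patients),
                 visits = sum(visit_counts(gen$cohort))))
  message(sprintf("simulate: %d patients, %d visits -> %s",
                  length(gen$cohort$patients), sum(visit_counts(gen$cohort)),
                  cohort_path))
  invisible(list(cohort = cohort_path, truth = truth_path))
}

#' Pipeline stage: cluster prescriptions and select k
#' @param cfg A [pipeline_config()].
#' @return The selected `herbrx_clusters` model (invisibly); side effects:
#'   model JSON, per-k selection summary CSV, difference-matrix CSV.
#' @export
pipeline_cluster <- function(cfg) {
  cohort_path <- file.path(cfg$outdir, "cohort.jsonl")
  if (!file.exists(cohort_path)) {
    stop("missing cohort; run pipeline_simulate() first", call. = FALSE)
  }
  ch <- read_cohort(cohort_path, "jsonl")
  mat <- build_prescription_matrix(ch)
  sel <- select_cluster_number(mat, cfg$cluster$k_grid, seed = cfg$seed)
  model <- sel$models[[as.character(sel$best_k)]]
  write_cluster_model(model, file.path(cfg$outdir, "cluster_model.json"))
  utils::write.csv(sel$summary, file.path(cfg$outdir, "cluster_selection.csv"),
                   row.names = FALSE)
  diff <- pairwise_cluster_difference(model, mat)
  utils::write.csv(diff, file.path(cfg$outdir, "cluster_difference.csv"),
                   row.names = FALSE)
  .manifest(cfg$outdir, "cluster", cfg,
            list(distinct_prescriptions = nrow(mat$x), best_k = sel$best_k))
  message(sprintf("cluster: %d distinct prescriptions, best k = %d",
                  nrow(mat$x), sel$best_k))
  invisible(model)
}

#' Pipeline stage: build the tetrad bank (virtual environment)
#' @param cfg A [pipeline_config()].
#' @return The `herbrx_tetrad_bank` (invisibly); side effect: tetrad JSONL.
#' @export
pipeline_build_env <- function(cfg) {
  cohort_path <- file.path(cfg$outdir, "cohort.jsonl")
  model_path <- file.path(cfg$outdir, "cluster_model.json")
  if (!file.exists(model_path)) {
    stop("missing cluster model; run pipeline_cluster() first", call. = FALSE)
  }
  ch <- read_cohort(cohort_path, "jsonl")
  model <- read_cluster_model(model_path)
  multi <- filter_multivisit(ch)
  train <- split_cohort(multi, cfg$train_fraction, seed = cfg$seed)$train
  bank <- build_tetrads(train, model, cfg$reward)
  write_tetrads(bank, file.path(cfg$outdir, "tetrads.jsonl"))
  .manifest(cfg$outdir, "build-env", cfg,
            list(multivisit_patients = length(multi$patients),
                 train_patients = length(train$patients),
                 tetrads = n_tetrads(bank)))
  message(sprintf("build-env: %d multivisit patients -> %d training tetrads",
                  length(multi$patients), n_tetrads(bank)))
  invisible(bank)
}

.pipeline_env <- function(cfg) {
  bank <- read_tetrads(file.path(cfg$outdir, "tetrads.jsonl"))
  model <- read_cluster_model(file.path(cfg$outdir, "cluster_model.json"))
  virtual_env(bank, model, cfg$reward, cfg$termination)
}

#' Pipeline stage: train an agent
#' @param cfg A [pipeline_config()].
#' @param kind `"dqn"` or `"drqn"`.
#' @return The trained `herbrx_agent` (invisibly); side effects: checkpoint
#'   + JSON sidecar + training-curve CSV.
#' @export
pipeline_train <- function(cfg, kind = c("dqn", "drqn")) {
  kind <- match.arg(kind)
  if (!file.exists(file.path(cfg$outdir, "tetrads.jsonl"))) {
    stop("missing tetrad bank; run pipeline_build_env() first", call. = FALSE)
  }
  env <- .pipeline_env(cfg)
  ch <- read_cohort(file.path(cfg$outdir, "cohort.jsonl"), "jsonl")
  multi <- filter_multivisit(ch)
  train <- split_cohort(multi, cfg$train_fraction, seed = cfg$seed)$train
  starts <- do.call(rbind, lapply(train$patients, function(p)
    encode_state(p$visits[[1L]], ch$symptom_vocab)))
  spec <- if (kind == "dqn") {
    qnetwork_spec("dqn", ncol(starts), cfg$agents$hidden_dqn,
                  n_actions = env$model$k)
  } else {
    qnetwork_spec("drqn", ncol(starts), cfg$agents$hidden_drqn,
                  recurrent_size = cfg$agents$recurrent_size,
                  n_actions = env$model$k)
  }
  tcfg <- do.call(train_config,
                  utils::modifyList(list(seed = cfg$seed), cfg$agents$train))
  agent <- train_agent(env, starts, spec, tcfg)
  save_agent(agent, file.path(cfg$outdir, paste0("agent_", kind, ".rds")))
  utils::write.csv(agent$curve,
                   file.path(cfg$outdir, paste0("curve_", kind, ".csv")),
                   row.names = FALSE)
  .manifest(cfg$outdir, paste0("train-", kind), cfg,
            list(episodes = tcfg$n_episodes,
                 parameters = agent_parameter_count(agent)))
  message(sprintf("train %s: %d episodes, %d parameters", kind,
                  tcfg$n_episodes, agent_parameter_count(agent)))
  invisible(agent)
}

#' Pipeline stage: evaluate trained agents against the clinician baseline
#' @param cfg A [pipeline_config()].
#' @return The return report data frame (invisibly); side effect: CSV.
#' @export
pipeline_evaluate <- function(cfg) {
  if (!file.exists(file.path(cfg$outdir, "tetrads.jsonl"))) {
    stop("missing tetrad bank; run pipeline_build_env() first", call. = FALSE)
  }
  env <- .pipeline_env(cfg)
  ch <- read_cohort(file.path(cfg$outdir, "cohort.jsonl"), "jsonl")
  multi <- filter_multivisit(ch)
  test <- split_cohort(multi, cfg$train_fraction, seed = cfg$seed)$test
  values <- list(doctor = doctor_returns(test, cfg$reward))
  for (kind in cfg$agents$kinds) {
    path <- file.path(cfg$outdir, paste0("agent_", kind, ".rds"))
    if (!file.exists(path)) {
      stop(sprintf("missing %s checkpoint; run pipeline_train(cfg, \"%s\") first",
                   kind, kind), call. = FALSE)
    }
    agent <- load_agent(path)
    values[[kind]] <- list(ssr = policy_ssr(agent, test, env),
                           scr = policy_scr(agent, test, env),
                           mcr = policy_mcr(agent, test, env)$mcr)
  }
  rnd <- uniform_policy(env$model$k)
  values$random <- list(ssr = policy_ssr(rnd, test, env, seed = cfg$seed),
                        scr = policy_scr(rnd, test, env, seed = cfg$seed),
                        mcr = policy_mcr(rnd, test, env, seed = cfg$seed)$mcr)
  report <- return_report(values)
  utils::write.csv(report, file.path(cfg$outdir, "return_report.csv"),
                   row.names = FALSE)
  .manifest(cfg$outdir, "evaluate", cfg,
            list(test_patients = length(test$patients)))
  message(paste(utils::capture.output(print(report)), collapse = "\n"))
  invisible(report)
}

#' Pipeline stage: recommendation experiment
#' @param cfg A [pipeline_config()].
#' @return The experiment data frame (invisibly); side effect: CSV.
#' @export
pipeline_recommend <- function(cfg) {
  model_path <- file.path(cfg$outdir, "cluster_model.json")
  if (!file.exists(model_path)) {
    stop("missing cluster model; run pipeline_cluster() first", call. = FALSE)
  }
  ch <- read_cohort(file.path(cfg$outdir, "cohort.jsonl"), "jsonl")
  model <- read_cluster_model(model_path)
  res <- run_recommendation_experiment(
    ch, model, thresholds = cfg$recommender$thresholds,
    hidden_sizes = cfg$recommender$hidden_sizes,
    epochs = cfg$recommender$epochs,
    train_fraction = cfg$train_fraction, seed = cfg$seed)
  utils::write.csv(res, file.path(cfg$outdir, "recommendation_report.csv"),
                   row.names = FALSE)
  .manifest(cfg$outdir, "recommend", cfg,
            list(thresholds = length(cfg$recommender$thresholds)))
  invisible(res)
}

#' Pipeline stage: consolidated markdown report
#' @param cfg A [pipeline_config()].
#' @return Path of the markdown report (invisibly).
#' @export
pipeline_report <- function(cfg) {
  ret_path <- file.path(cfg$outdir, "return_report.csv")
  rec_path <- file.path(cfg$outdir, "recommendation_report.csv")
  if (!file.exists(ret_path)) {
    stop("missing return report; run pipeline_evaluate() first", call. = FALSE)
  }
  ret <- utils::read.csv(ret_path)
  fmt_row <- function(r) {
    cell <- function(v, imp) {
      if (is.na(imp)) sprintf("%.2f", v) else sprintf("%.2f (%.0f%%)", v, imp)
    }
    sprintf("| %s | %s | %s | %s |", r$policy,
            cell(r$ssr, r$ssr_improvement_pct),
            cell(r$scr, r$scr_improvement_pct),
            cell(r$mcr, r$mcr_improvement_pct))
  }
  lines <- c("# Treatment-planning report", "",
             sprintf("Seed: %d", cfg$seed), "",
             "## Policy returns (improvement over the clinician baseline)", "",
             "| policy | SSR | SCR | MCR |", "| --- | --- | --- | --- |",
             vapply(seq_len(nrow(ret)), function(i) fmt_row(ret[i, ]),
                    character(1)))
  if (file.exists(rec_path)) {
    rec <- utils::read.csv(rec_path)
    lines <- c(lines, "", "## Herb recommendation", "",
               "| input | threshold | herbs (mean±sd) | P | R | F1 | IoU |",
               "| --- | --- | --- | --- | --- | --- | --- |",
               vapply(seq_len(nrow(rec)), function(i) {
                 r <- rec[i, ]
                 sprintf("| %s | %.1f | %.2f±%.2f | %.2f | %.2f | %.2f | %.2f |",
                         r$input_mode, r$filter_threshold, r$n_herbs_mean,
                         r$n_herbs_sd, r$precision, r$recall, r$f1, r$iou)
               }, character(1)))
  }
  path <- file.path(cfg$outdir, "report.md")
  writeLines(lines, path, useBytes = TRUE)
  .manifest(cfg$outdir, "report", cfg, list(sections = 2L))
  invisible(path)
}

#' Run the full pipeline end to end
#' @param cfg A [pipeline_config()].
#' @return Named list with the evaluation and recommendation reports.
#' @export
run_pipeline <- function(cfg) {
  pipeline_simulate(cfg)
  pipeline_cluster(cfg)
  pipeline_build_env(cfg)
  for (kind in cfg$agents$kinds) pipeline_train(cfg, kind)
  out <- list(returns = pipeline_evaluate(cfg),
              recommendation = pipeline_recommend(cfg))
  pipeline_report(cfg)
  out
}
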