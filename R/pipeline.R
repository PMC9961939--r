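# Pipeline orchestration: runs simulate -> cohort -> features -> mdp ->
# train -> evaluate -> explain from a single nested configuration, writing
# delimited-text/JSON artifacts and a validated run report.

PIPELINE_STAGES <- c("simulate", "cohort", "features", "mdp", "train",
                     "evaluate", "explain", "report")

#' Assemble a pipeline run configuration
#'
#' Nested configuration covering every stage. Unknown top-level keys are
#' rejected; each section is merged over the package defaults.
#'
#' @param config named list (or path to a YAML file) with any of the sections
#'   `simulate` (arguments of [sim_config()]), `cohort`
#'   (`window_before_h`, `window_after_h`), `features`
#'   (`coverage_threshold`), `mdp` (`gamma`, `fractions`), `train`
#'   (arguments of [train_config()]), `ope` (`c`, `delta`, `method`,
#'   `p_min`, `split`), `explain` (`epsilon`, `num_trees`,
#'   `n_relevance_states`), plus a global `seed`
#' @return a validated `run_config` list
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulate", "cohort", "features", "mdp", "train", "ope",
             "explain", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stopf("unknown configuration section(s): %s", paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  defaults <- list(
    simulate = list(n_admissions = 200L, seed = seed),
    cohort = list(window_before_h = 24, window_after_h = 72),
    features = list(coverage_threshold = 0.02),
    mdp = list(gamma = 0.99,
               fractions = c(train = 0.7, validation = 0.2, test = 0.1)),
    train = list(seed = seed),
    ope = list(c = 100, delta = 0.05, method = "concentration",
               p_min = 0.01, split = "validation"),
    explain = list(epsilon = 0.01, num_trees = 500L,
                   n_relevance_states = 200L))
  out <- lapply(names(defaults), function(s)
    utils::modifyList(defaults[[s]], config[[s]] %||% list()))
  names(out) <- names(defaults)
  out$seed <- seed
  class(out) <- "run_config"
  out
}

stage_inputs <- function(stage) {
  switch(stage,
    simulate = character(),
    cohort = c("admissions.csv", "events.csv"),
    features = c("admissions.csv", "events.csv", "episodes.csv", "splits.csv"),
    mdp = c("admissions.csv", "events.csv", "episodes.csv", "states.csv",
            "splits.csv"),
    train = c("states.csv", "actions.csv", "admissions.csv", "splits.csv"),
    evaluate = c("states.csv", "actions.csv", "admissions.csv", "splits.csv",
                 "model.json", "episodes.csv"),
    explain = c("states.csv", "actions.csv", "admissions.csv", "splits.csv",
                "model.json"),
    report = c("episodes.csv", "splits.csv", "training_log.csv",
               "ope_report.json"))
}

stage_producing <- function(artifact) {
  map <- c(admissions.csv = "simulate", events.csv = "simulate",
           ground_truth.csv = "simulate", episodes.csv = "cohort",
           splits.csv = "cohort", states.csv = "features",
           feature_spec.json = "features", actions.csv = "mdp",
           trajectories.jsonl = "mdp", model.json = "train",
           training_log.csv = "train", ope_report.json = "evaluate",
           concordance_outcomes.csv = "evaluate", day_curves.csv = "evaluate",
           rankings.csv = "explain", clone_metrics.json = "explain")
  unname(map[artifact])
}

require_artifacts <- function(out_dir, stage) {
  needed <- stage_inputs(stage)
  missing <- needed[!file.exists(file.path(out_dir, needed))]
  if (length(missing))
    stopf("stage '%s' needs %s; run stage '%s' first",
          stage, paste(missing, collapse = ", "),
          paste(unique(stage_producing(missing)), collapse = ", "))
}

read_admissions <- function(out_dir) {
  a <- data.table::fread(file.path(out_dir, "admissions.csv"))
  a[, admitted_at := as.POSIXct(admitted_at, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%SZ")]
  a[, discharged_at := as.POSIXct(discharged_at, tz = "UTC",
                                  format = "%Y-%m-%dT%H:%M:%SZ")]
  a
}

read_events <- function(out_dir) {
  e <- data.table::fread(file.path(out_dir, "events.csv"))
  e[, timestamp := as.POSIXct(timestamp, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%SZ")]
  e
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

log_stage <- function(out_dir, stage, msg, level = "INFO") {
  line <- sprintf("[%s] %s %s: %s", level,
                  format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Run the treatment-policy pipeline
#'
#' Executes the stages `simulate`, `cohort`, `features`, `mdp`, `train`,
#' `evaluate`, `explain` and `report` in order (any subset, provided the
#' upstream artifacts already exist in `out_dir`), writing every artifact as
#' delimited text or JSON and finally a validated `run_report.json` stamped
#' with the configuration hash and seed.
#'
#' @param config a [run_config()], a raw list, or a YAML path
#' @param out_dir output directory
#' @param stages subset of stages to run (default: all)
#' @return invisibly, the run report list (when the report stage ran)
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = PIPELINE_STAGES) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- NULL
  for (stage in stages) {
    require_artifacts(out_dir, stage)
    t0 <- Sys.time()
    switch(stage,
      simulate = {
        sim_cfg <- do.call(sim_config, config$simulate)
        cohort <- generate_cohort(sim_cfg)
        write_synthetic_ehr(cohort, out_dir)
        log_stage(out_dir, stage, sprintf("%d admissions, %d events",
                  nrow(cohort$admissions), nrow(cohort$events)))
      },
      cohort = {
        adm <- read_admissions(out_dir); ev <- read_events(out_dir)
        sofa <- compute_sofa_daily(ev, adm)
        susp <- detect_suspected_infection(ev,
                  config$cohort$window_before_h, config$cohort$window_after_h)
        ep <- identify_sepsis(sofa, susp, adm)
        ep <- flag_septic_shock(ep, ev)
        data.table::fwrite(ep, file.path(out_dir, "episodes.csv"))
        data.table::fwrite(sofa, file.path(out_dir, "sofa_daily.csv"))
        included <- ep[included == TRUE, admission_id]
        splits <- split_admissions(included,
                                   fractions = config$mdp$fractions,
                                   seed = config$seed)
        data.table::fwrite(splits, file.path(out_dir, "splits.csv"))
        log_stage(out_dir, stage, sprintf("%d/%d admissions included",
                  length(included), nrow(adm)))
      },
      features = {
        adm <- read_admissions(out_dir); ev <- read_events(out_dir)
        ep <- data.table::fread(file.path(out_dir, "episodes.csv"))
        splits <- data.table::fread(file.path(out_dir, "splits.csv"))
        train_ids <- splits[split == "train", admission_id]
        ds <- build_daily_states(ev, ep, adm, train_ids,
                                 config$features$coverage_threshold)
        data.table::fwrite(ds$states, file.path(out_dir, "states.csv"))
        write_feature_fit(ds$fit, file.path(out_dir, "feature_spec.json"))
        log_stage(out_dir, stage,
                  sprintf("%d features, %d admission-days, %.2f%% imputed",
                          length(ds$feature_names), nrow(ds$states),
                          100 * ds$imputed_fraction))
      },
      mdp = {
        adm <- read_admissions(out_dir); ev <- read_events(out_dir)
        ep <- data.table::fread(file.path(out_dir, "episodes.csv"))
        st <- data.table::fread(file.path(out_dir, "states.csv"))
        actions <- daily_steroid_dose(ev, ep, adm)
        data.table::fwrite(actions, file.path(out_dir, "actions.csv"))
        traj <- build_trajectories(st, actions, adm, gamma = config$mdp$gamma)
        write_trajectories(traj, file.path(out_dir, "trajectories.jsonl"))
        log_stage(out_dir, stage, sprintf("%d trajectories, %d day-states",
                  traj$n_traj, nrow(traj$X)))
      },
      train = {
        parts <- load_trajectory_splits(out_dir, config)
        tc <- do.call(train_config,
                      utils::modifyList(list(gamma = config$mdp$gamma),
                                        config$train))
        fit <- train_actor_critic(parts$train, tc, valid = parts$validation)
        write_model(fit$model, file.path(out_dir, "model.json"))
        data.table::fwrite(fit$log, file.path(out_dir, "training_log.csv"))
        log_stage(out_dir, stage,
                  sprintf("%d epochs, final relative error %.4f, concordance %.3f",
                          nrow(fit$log), fit$log$relative_error[nrow(fit$log)],
                          fit$log$concordance[nrow(fit$log)]))
      },
      evaluate = {
        parts <- load_trajectory_splits(out_dir, config)
        model <- read_model(file.path(out_dir, "model.json"))
        ep <- data.table::fread(file.path(out_dir, "episodes.csv"))
        clone <- fit_behavior_clone(parts$train, parts$validation,
                                    num_trees = config$explain$num_trees,
                                    seed = config$seed)
        b <- estimate_behavior_policy(clone, p_min = config$ope$p_min)
        eval_traj <- parts[[config$ope$split]]
        rep_ope <- ope_report(eval_traj,
                              policy_probs(model, eval_traj$X),
                              b$predict(eval_traj$X),
                              c = config$ope$c, delta = config$ope$delta,
                              method = config$ope$method)
        jsonlite::write_json(rep_ope[setdiff(names(rep_ope), "weights")],
                             file.path(out_dir, "ope_report.json"),
                             auto_unbox = TRUE, digits = NA)
        co <- concordance_outcomes(model, parts$test, ep)
        data.table::fwrite(co, file.path(out_dir, "concordance_outcomes.csv"))
        curves <- policy_comparison_curves(model, parts$test)
        data.table::fwrite(curves, file.path(out_dir, "day_curves.csv"))
        log_stage(out_dir, stage, sprintf("J_e=%.3f, J_b=%.3f, bound=%.3f",
                  rep_ope$point_estimate, rep_ope$behavior_estimate,
                  rep_ope$lower_bound_95))
      },
      explain = {
        parts <- load_trajectory_splits(out_dir, config)
        model <- read_model(file.path(out_dir, "model.json"))
        n_states <- min(config$explain$n_relevance_states,
                        nrow(parts$train$X))
        ix <- with_seed(config$seed, sample.int(nrow(parts$train$X), n_states))
        M <- lrp_relevance_matrix(model, parts$train$X[ix, , drop = FALSE],
                                  epsilon = config$explain$epsilon)
        agent_rank <- aggregate_relevance(M)
        clone <- fit_behavior_clone(parts$train, parts$validation,
                                    num_trees = config$explain$num_trees,
                                    seed = config$seed)
        cmp <- compare_rankings(agent_rank, clone)
        data.table::fwrite(cmp$table, file.path(out_dir, "rankings.csv"))
        jsonlite::write_json(list(auroc_micro = clone$auroc_micro,
                                  confusion = clone$confusion,
                                  spearman = cmp$spearman),
                             file.path(out_dir, "clone_metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        log_stage(out_dir, stage, sprintf("clone AUROC %.3f, Spearman %.3f",
                  clone$auroc_micro, cmp$spearman))
      },
      report = {
        report <- build_run_report(out_dir, config)
        validate_run_report(report)
        jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                             auto_unbox = TRUE, digits = NA)
        log_stage(out_dir, stage, "run_report.json written")
      })
    log_stage(out_dir, stage, sprintf("done in %.1fs",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(report)
}

# reload states/actions/admissions and split them into trajectory sets
load_trajectory_splits <- function(out_dir, config) {
  adm <- read_admissions(out_dir)
  st <- data.table::fread(file.path(out_dir, "states.csv"))
  actions <- data.table::fread(file.path(out_dir, "actions.csv"))
  splits <- data.table::fread(file.path(out_dir, "splits.csv"))
  traj <- build_trajectories(st, actions, adm, gamma = config$mdp$gamma)
  out <- lapply(c(train = "train", validation = "validation", test = "test"),
                function(s) subset_trajectories(
                  traj, splits[split == s, admission_id]))
  out$all <- traj
  out
}

build_run_report <- function(out_dir, config) {
  ep <- data.table::fread(file.path(out_dir, "episodes.csv"))
  adm <- read_admissions(out_dir)
  sofa <- data.table::fread(file.path(out_dir, "sofa_daily.csv"))
  splits <- data.table::fread(file.path(out_dir, "splits.csv"))
  tl <- data.table::fread(file.path(out_dir, "training_log.csv"))
  ope <- jsonlite::read_json(file.path(out_dir, "ope_report.json"),
                             simplifyVector = TRUE)
  rank_path <- file.path(out_dir, "rankings.csv")
  top_feats <- if (file.exists(rank_path)) {
    rk <- data.table::fread(rank_path)
    list(agent = utils::head(rk[order(agent_rank), feature], 20),
         clinician = utils::head(rk[order(clone_rank), feature], 20))
  } else NULL
  last <- tl[nrow(tl)]
  counts <- as.list(table(ep$exclusion_reason))
  list(schema_version = "1.0",
       config_hash = config_hash(unclass(config)),
       seed = config$seed,
       cohort = list(n_admissions = nrow(adm),
                     n_included = sum(ep$included),
                     exclusions = counts,
                     table1 = summarize_cohort(adm, ep, sofa)),
       splits = as.list(table(splits$split)),
       training = list(epochs = nrow(tl),
                       final_relative_error = last$relative_error,
                       final_concordance = last$concordance,
                       action_distribution = list(
                         initial = as.numeric(tl[1, .(a0, a1, a2, a3, a4)]),
                         final = as.numeric(last[, .(a0, a1, a2, a3, a4)]))),
       ope = ope,
       top_features = top_feats)
}

#' Validate a run report against its schema
#'
#' Checks the presence and types of the required fields of the versioned run
#' report.
#' @param report a run report list
#' @return invisibly `TRUE`; errors if invalid
#' @export
validate_run_report <- function(report) {
  need <- c("schema_version", "config_hash", "seed", "cohort", "splits",
            "training", "ope")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stopf("run report missing field(s): %s", paste(missing, collapse = ", "))
  if (!identical(report$schema_version, "1.0"))
    stopf("unsupported run report schema version: %s", report$schema_version)
  if (!is.numeric(report$ope$point_estimate %||% ope_num(report)))
    stopf("run report: OPE point estimate missing")
  invisible(TRUE)
}

ope_num <- function(report) report$ope[["point_estimate"]]
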