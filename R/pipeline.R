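#' Derive a stage seed from the global seed
#'
#' Pure function of (global seed, stage name): a small polynomial hash of
#' the stage name folded into the global seed, kept below 2^31.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name string.
#' @return Integer stage seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% 1000003
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

#' Validate and complete a run configuration
#'
#' Reads a YAML or JSON run configuration (or takes a list), fills every
#' default, and collects range/type errors. Recognized top-level keys:
#' `cohort`, `panel`, `grid`, `variants`, `bootstrap`, `global_seed`.
#' An empty file yields the defaults-complete configuration.
#'
#' @param config Path to a YAML/JSON file, or a list.
#' @return A `run_config` list; invalid input raises an error listing every
#'   problem found.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  errors <- character()
  known <- c("cohort", "panel", "grid", "variants", "bootstrap", "global_seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown top-level key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  gs <- config$global_seed %||% 1L
  if (!is.numeric(gs) || length(gs) != 1L) {
    errors <- c(errors, "global_seed must be a single integer")
    gs <- 1L
  }
  co <- config$cohort %||% list()
  tf <- co$train_fraction %||% 0.8
  if (!is.numeric(tf) || tf <= 0 || tf >= 1) {
    errors <- c(errors, "cohort$train_fraction must lie in (0, 1)")
  }
  cohort <- tryCatch(
    default_cohort_config(
      seed = stage_seed(gs, "simulate"),
      n_intubations = co$n_intubations %||% 1000,
      n_external = co$n_external %||% 250,
      train_fraction = if (is.numeric(tf) && tf > 0 && tf < 1) tf else 0.8,
      n_lags = co$n_lags %||% 2),
    error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  pn <- config$panel %||% list()
  panel <- tryCatch(
    expert_panel_config(
      perception_noise_sd = pn$perception_noise_sd %||% 0.25,
      shared_bias = pn$shared_bias %||% 0,
      seed = stage_seed(gs, "panel")),
    error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  gr <- config$grid %||% list()
  grid <- tryCatch(
    hyperparam_grid(
      learning_rates = gr$learning_rates %||% 0.1,
      num_leaves = gr$num_leaves %||% 4,
      n_trees = gr$n_trees %||% 32,
      n_folds = gr$n_folds %||% 3,
      seed = stage_seed(gs, "tune")),
    error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  va <- config$variants %||% list()
  ks <- va$ks %||% c(1, 3, 5, 7, 10, 11)
  if (!is.numeric(ks) || any(ks < 0) || any(ks != floor(ks))) {
    errors <- c(errors, "variants$ks must be non-negative integers")
  }
  bs <- config$bootstrap %||% list()
  bspec <- tryCatch(
    bootstrap_spec(n_iterations = bs$n_iterations %||% 2000,
                   resample_unit = bs$resample_unit %||% "intubation",
                   seed = stage_seed(gs, "bootstrap")),
    error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  if (length(errors)) {
    stop(paste(c("invalid run configuration:", paste("-", errors)),
               collapse = "\n"), call. = FALSE)
  }
  structure(list(cohort = cohort, panel = panel, grid = grid,
                 variants = list(ks = as.integer(ks), include_soft = TRUE),
                 bootstrap = bspec, global_seed = as.integer(gs)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full expert-augmented pipeline
#'
#' Executes the stages in order — simulate cohort, fit the rule ensemble,
#' render the survey, simulate (or ingest) the expert panel, aggregate and
#' compute discordance, refit the expert-augmented variants, and evaluate
#' all models — writing every artifact plus a manifest with md5 hashes to
#' `output_dir`. When `responses_file` is supplied the panel-simulation
#' stage is skipped and the responses are ingested instead.
#'
#' @param config A `run_config` from [validate_config()].
#' @param output_dir Directory for artifacts (created if needed).
#' @param responses_file Optional CSV of real expert responses.
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir, responses_file = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(output_dir, f)
  artifacts <- character()
  note <- function(msg, ...) message(sprintf(paste0("[eamlr] ", msg), ...))
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- run_stage("simulate", function() generate_cohort(config$cohort))
  write_cohort_csv(cohort, path("cohort.csv"))
  artifacts <- c(artifacts, "cohort.csv")
  train <- cohort_split(cohort, "train")
  test <- cohort_split(cohort, "test")
  external <- cohort_split(cohort, "external")
  note("simulated cohort: %d train / %d test / %d external windows",
       nrow(train), nrow(test), nrow(external))

  hp <- run_stage("tune", function() tune_hyperparameters(train, config$grid))
  model <- run_stage("fit", function() {
    fit_rulefit(train, hp, seed = stage_seed(config$global_seed, "fit"))
  })
  write_rulefit_model(model, path("rulefit_model.json"))
  artifacts <- c(artifacts, "rulefit_model.json")
  note("rule ensemble: %d candidate rules, %d selected",
       length(model$all_rules), length(model$selected_ids))

  form <- run_stage("survey", function() {
    render_survey(model, train = train,
                  seed = stage_seed(config$global_seed, "survey"),
                  json_path = path("survey.json"), md_path = path("survey.md"))
  })
  artifacts <- c(artifacts, "survey.json", "survey.md")

  if (is.null(responses_file)) {
    responses <- run_stage("panel", function() {
      simulate_expert_panel(model$selected_rules, cohort, config$panel)
    })
    responses_source <- "simulated panel"
  } else {
    responses <- run_stage("ingest", function() {
      ingest_responses(responses_file, form)
    })
    responses_source <- "external responses"
  }
  write_responses_csv(responses, path("responses.csv"))
  artifacts <- c(artifacts, "responses.csv")
  note("responses: %d rows from %s", nrow(responses), responses_source)

  agg <- run_stage("aggregate", function() aggregate_responses(responses))
  assessments <- run_stage("discord", function() {
    assess_rules(model, train, agg)
  })
  write_assessments_csv(assessments, path("assessments.csv"),
                        rules = model$selected_rules)
  artifacts <- c(artifacts, "assessments.csv")

  variants <- run_stage("refit", function() {
    fit_eaml_variants(model, train, assessments, ks = config$variants$ks,
                      include_soft = config$variants$include_soft,
                      seed = stage_seed(config$global_seed, "refit"))
  })
  write_eaml_models(variants, path("eaml_models.json"))
  artifacts <- c(artifacts, "eaml_models.json")
  hard_models <- variants[grepl("^hard_", names(variants))]
  for (nm in names(hard_models)) {
    note("%s excluded rules: %s", nm,
         paste(hard_models[[nm]]$excluded_rules, collapse = ", "))
  }

  rep <- run_stage("evaluate", function() {
    full_report(c(list(rulefit = model), variants), test, external, train,
                config$bootstrap)
  })
  utils::write.csv(as.data.frame(rep$report), path("report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep$report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  utils::write.csv(as.data.frame(rep$roc), path("roc_curves.csv"),
                   row.names = FALSE)
  artifacts <- c(artifacts, "report.csv", "report.json", "roc_curves.csv")

  cfg_path <- path("config.json")
  jsonlite::write_json(list(global_seed = config$global_seed,
                            variants = config$variants,
                            bootstrap = unclass(config$bootstrap)),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, "config.json")

  hashes <- tools::md5sum(vapply(artifacts, path, character(1)))
  manifest <- list(package_version = as.character(utils::packageVersion("eamlr")),
                   global_seed = config$global_seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   responses_source = responses_source,
                   artifacts = as.list(stats::setNames(unname(hashes), artifacts)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  structure(manifest, class = "run_manifest")
}
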