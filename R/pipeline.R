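#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML (or already-parsed list) with sections:
#' \describe{
#'   \item{scenario}{`train_preset` / `test_preset` (or custom generator
#'     parameters `n_plots`, `priors`, `class_counts`, `cloud_prob`,
#'     `calendar_from`, `calendar_to`).}
#'   \item{combinations}{Character vector of scheme ids, subset of C1..C4.}
#'   \item{classifier}{`algorithm` plus any [classifier_spec()] fields.}
#'   \item{soil_line}{`source: fixed` with `slope`, or `source: bare_plots`
#'     with `n_bare` (synthetic bare plots are generated and the slope
#'     estimated by the ratio-of-sums estimator).}
#'   \item{emergence_threshold}{WDVI threshold (default 0.005).}
#'   \item{seed}{Root seed; every stochastic stage derives its own seed from
#'     it.}
#' }
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list of class `"run_config"`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$scenario)) stop("config missing the scenario section")
  if (is.null(config$soil_line) || is.null(config$soil_line$source)) {
    stop("config missing the soil_line source (fixed slope or bare_plots)")
  }
  src <- config$soil_line$source
  if (!src %in% c("fixed", "bare_plots")) {
    stop("soil_line source must be 'fixed' or 'bare_plots'")
  }
  if (src == "fixed" && is.null(config$soil_line$slope)) {
    stop("soil_line source 'fixed' requires a slope")
  }
  config$combinations <- config$combinations %||% c("C1", "C2", "C3", "C4")
  bad <- setdiff(config$combinations, c("C1", "C2", "C3", "C4"))
  if (length(bad) > 0) stop("unknown combinations: ", paste(bad, collapse = ", "))
  config$classifier <- config$classifier %||% list(algorithm = "svm_cubic")
  config$emergence_threshold <- config$emergence_threshold %||% 0.005
  config$seed <- config$seed %||% 1
  class(config) <- c("run_config", "list")
  config
}

scenario_from_config <- function(sc, role) {
  preset <- sc[[paste0(role, "_preset")]]
  if (!is.null(preset)) return(scenario_config(preset = preset))
  if (role == "test") return(NULL)
  cal <- regular_calendar(sc$calendar_from %||% "2019-04-02",
                          sc$calendar_to %||% "2019-09-04",
                          cloud_prob = sc$cloud_prob %||% 0,
                          seed = sc$calendar_seed %||% 1)
  scenario_config(n_plots = sc$n_plots,
                  class_counts = unlist(sc$class_counts),
                  priors = unlist(sc$priors), calendar = cal,
                  split_fraction = sc$split_fraction %||% 0.5)
}

artifact <- function(outdir, name) file.path(outdir, name)

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s': run the '%s' stage first",
                 basename(path), produced_by), call. = FALSE)
  }
  path
}

read_scenario_artifacts <- function(outdir, role, stage_name = "simulate") {
  refl <- utils::read.csv(
    require_artifact(artifact(outdir, paste0(role, "_reflectance.csv")), stage_name)
  )
  refl$date <- as.Date(refl$date)
  cal <- utils::read.csv(
    require_artifact(artifact(outdir, paste0(role, "_calendar.csv")), stage_name)
  )
  plots <- utils::read.csv(
    require_artifact(artifact(outdir, paste0(role, "_plots.csv")), stage_name)
  )
  list(reflectance = refl,
       calendar = acquisition_calendar(as.Date(cal$date), cal$cloudy == 1),
       plots = plots)
}

write_calendar_csv <- function(calendar, path) {
  utils::write.csv(data.frame(date = format(calendar$date),
                              cloudy = as.integer(calendar$cloudy)),
                   path, row.names = FALSE)
}

log_msg <- function(outdir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  message(msg)
  cat(msg, "\n", file = artifact(outdir, "run.log"), append = TRUE)
}

stage_simulate <- function(config, outdir) {
  seed <- config$seed
  train <- generate_dataset(scenario_from_config(config$scenario, "train"), seed)
  utils::write.csv(train$reflectance, artifact(outdir, "train_reflectance.csv"),
                   row.names = FALSE)
  utils::write.csv(train$plots, artifact(outdir, "train_plots.csv"),
                   row.names = FALSE)
  write_calendar_csv(train$calendar, artifact(outdir, "train_calendar.csv"))
  counts <- list(train_records = nrow(train$reflectance))
  test_cfg <- scenario_from_config(config$scenario, "test")
  if (!is.null(test_cfg)) {
    test <- generate_dataset(test_cfg, (seed + 104729) %% 2147483647)
    utils::write.csv(test$reflectance, artifact(outdir, "test_reflectance.csv"),
                     row.names = FALSE)
    utils::write.csv(test$plots, artifact(outdir, "test_plots.csv"),
                     row.names = FALSE)
    write_calendar_csv(test$calendar, artifact(outdir, "test_calendar.csv"))
    counts$test_records <- nrow(test$reflectance)
  }
  log_msg(outdir, "simulate: %d training records", counts$train_records)
  counts
}

resolve_soil_line <- function(config, outdir) {
  sl <- config$soil_line
  if (sl$source == "fixed") return(soil_line(sl$slope))
  bare <- simulate_bare_plots(sl$n_bare %||% 100,
                              noise_sd = sl$noise_sd %||% 0.005,
                              seed = derive_seed(config$seed, "bare"))
  estimate_soil_line(bare)
}

stage_features <- function(config, outdir) {
  train <- read_scenario_artifacts(outdir, "train")
  line <- resolve_soil_line(config, outdir)
  jsonlite::write_json(list(slope_a = line$slope_a, intercept = line$intercept,
                            source = config$soil_line$source),
                       artifact(outdir, "soil_line.json"), auto_unbox = TRUE,
                       digits = NA)
  feats <- compute_features(train$reflectance, line, config$emergence_threshold)
  utils::write.csv(feats, artifact(outdir, "train_features.csv"), row.names = FALSE)
  log_msg(outdir, "features: soil-line slope %.4f, %d feature rows",
          line$slope_a, nrow(feats))
  list(feature_rows = nrow(feats), slope_a = line$slope_a)
}

read_soil_line <- function(outdir, stage_name = "features") {
  sl <- jsonlite::read_json(require_artifact(artifact(outdir, "soil_line.json"),
                                             stage_name))
  soil_line(sl$slope_a, sl$intercept)
}

stage_stack <- function(config, outdir) {
  train <- read_scenario_artifacts(outdir, "train")
  require_artifact(artifact(outdir, "train_features.csv"), "features")
  line <- read_soil_line(outdir)
  train_ids <- train$plots$plot_id[!is.na(train$plots$split) &
                                     train$plots$split == "train"]
  if (length(train_ids) == 0) train_ids <- train$plots$plot_id
  counts <- list()
  for (cid in config$combinations) {
    spec <- combination_spec(cid)
    tab <- assemble_training_table(train, spec, line,
                                   threshold = config$emergence_threshold,
                                   plot_ids = train_ids)
    out <- artifact(outdir, sprintf("training_table_%s.csv", cid))
    utils::write.csv(as.data.frame(tab), out, row.names = FALSE)
    jsonlite::write_json(
      list(combination = cid, lags = spec$lags, tolerance = spec$tolerance,
           emergence_threshold = config$emergence_threshold,
           descriptors = attr(tab, "descriptors"), n_records = nrow(tab)),
      artifact(outdir, sprintf("training_table_%s.meta.json", cid)),
      auto_unbox = TRUE)
    counts[[cid]] <- nrow(tab)
  }
  log_msg(outdir, "stack: records per combination: %s",
          paste(names(counts), unlist(counts), sep = "=", collapse = ", "))
  counts
}

classifier_from_config <- function(config) {
  cc <- config$classifier
  do.call(classifier_spec, c(
    list(algorithm = cc$algorithm %||% "svm_cubic"),
    cc[setdiff(names(cc), "algorithm")],
    if (is.null(cc$seed)) list(seed = config$seed)
  ))
}

stage_train <- function(config, outdir) {
  spec <- classifier_from_config(config)
  dir.create(artifact(outdir, "models"), showWarnings = FALSE)
  out <- list()
  for (cid in config$combinations) {
    path <- require_artifact(artifact(outdir, sprintf("training_table_%s.csv", cid)),
                             "stack")
    tab <- utils::read.csv(path)
    model <- train_classifier(tab, spec)
    mpath <- artifact(outdir, file.path("models",
                                        sprintf("%s_%s.rds", spec$algorithm, cid)))
    save_model(model, mpath)
    out[[cid]] <- mpath
  }
  log_msg(outdir, "train: %s fitted for %s", spec$algorithm,
          paste(config$combinations, collapse = ", "))
  out
}

stage_evaluate <- function(config, outdir) {
  spec <- classifier_from_config(config)
  train <- read_scenario_artifacts(outdir, "train")
  line <- read_soil_line(outdir)
  val_ids <- train$plots$plot_id[!is.na(train$plots$split) &
                                   train$plots$split == "validation"]
  rows <- list()
  for (cid in config$combinations) {
    mpath <- require_artifact(
      artifact(outdir, file.path("models", sprintf("%s_%s.rds", spec$algorithm, cid))),
      "train")
    model <- load_model(mpath)
    if (length(val_ids) == 0) next
    tab <- assemble_training_table(train, combination_spec(cid), line,
                                   threshold = config$emergence_threshold,
                                   plot_ids = val_ids)
    if (nrow(tab) == 0) next
    pred <- predict(model, tab)
    rep <- accuracy_report(confusion_counts(tab$crop_label, pred, model$classes))
    rows[[cid]] <- data.frame(combination = cid, n_records = rep$n,
                              overall_accuracy = rep$overall_accuracy,
                              kappa = rep$kappa, altman = rep$altman)
  }
  eval_tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(combination = character(0))
  utils::write.csv(eval_tab, artifact(outdir, "evaluation.csv"), row.names = FALSE)
  log_msg(outdir, "evaluate: %d combination(s) scored on the holdout split",
          nrow(eval_tab))
  eval_tab
}

stage_timeline <- function(config, outdir) {
  spec <- classifier_from_config(config)
  line <- read_soil_line(outdir)
  test <- read_scenario_artifacts(outdir, "test", "simulate (with a test scenario)")
  models <- list()
  for (cid in config$combinations) {
    mpath <- require_artifact(
      artifact(outdir, file.path("models", sprintf("%s_%s.rds", spec$algorithm, cid))),
      "train")
    models[[cid]] <- load_model(mpath)
  }
  tl <- timeline_evaluate(models, test, line,
                          threshold = config$emergence_threshold)
  tl$date <- format(tl$date)
  utils::write.csv(tl, artifact(outdir, "timeline.csv"), row.names = FALSE)
  log_msg(outdir, "timeline: %d (date, combination) evaluations", nrow(tl))
  tl
}

#' Run the crop-recognition pipeline
#'
#' Executes the stages simulate -> features -> stack -> train -> evaluate ->
#' timeline (or a single stage) against an output directory, writing each
#' stage's artifacts as CSV/JSON files plus a manifest with the config hash,
#' seed and row counts. Stages validate that their upstream artifacts exist
#' and fail naming the stage that must run first.
#'
#' @param config A [read_run_config()] result, a config list, or a YAML path.
#' @param stage `"all"` or one stage name.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list of per-stage summaries.
#' @export
run_pipeline <- function(config, stage = "all", outdir = "croprec_run",
                         seed = NULL) {
  config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stages <- c("simulate", "features", "stack", "train", "evaluate", "timeline")
  stage <- match.arg(stage, c("all", stages))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  run <- if (stage == "all") {
    has_test <- !is.null(config$scenario$test_preset)
    if (has_test) stages else setdiff(stages, "timeline")
  } else stage
  results <- list()
  for (s in run) {
    results[[s]] <- switch(s,
      simulate = stage_simulate(config, outdir),
      features = stage_features(config, outdir),
      stack = stage_stack(config, outdir),
      train = stage_train(config, outdir),
      evaluate = stage_evaluate(config, outdir),
      timeline = stage_timeline(config, outdir)
    )
  }
  manifest <- list(
    config_hash = rlang::hash(unclass(config)), seed = config$seed,
    stages_run = run,
    counts = lapply(results, function(r) if (is.data.frame(r)) nrow(r) else r),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, artifact(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
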