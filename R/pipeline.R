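# End-to-end workflow: simulate/load -> preprocess + features -> AUC
# screen -> false-label filter + PCA + classifier under LOSO -> group
# evaluation, with a run manifest that fully determines the outputs.

#' Configuration for a full pipeline run
#'
#' Collects every tunable of the workflow with its default: smoothing
#' window 29, baseline percentile 30, D thresholds +0.3 / -0.2, six
#' principal components, false-label fraction 0.10. All randomness flows
#' from the single `seed`, fanned out per stage.
#'
#' @param seed Root seed.
#' @param sim [simulation_config()] used when no cohort is supplied.
#' @param window,sigma,baseline_percentile,baseline_mode Preprocessing
#'   settings (see [normalize_session()]).
#' @param up_threshold,down_threshold D thresholds (see [cell_ratios()]).
#' @param n_components Principal components kept.
#' @param false_label_fraction Fraction of pain-labeled training sessions
#'   removed by the false-label filter.
#' @param filter_iterations Passes of the false-label filter.
#' @param classifier List of classifier settings: `size`, `decay`, `maxit`.
#' @param out_dir Optional output directory for the results bundle.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = simulation_config(seed = seed),
                            window = 29L, sigma = NULL,
                            baseline_percentile = 30,
                            baseline_mode = "subset-mean",
                            up_threshold = 0.3, down_threshold = -0.2,
                            n_components = 6L,
                            false_label_fraction = 0.10,
                            filter_iterations = 1L,
                            classifier = list(size = 8L, decay = 0.01,
                                              maxit = 500L),
                            out_dir = NULL) {
  cfg <- structure(
    list(seed = as.integer(seed), sim = sim, window = as.integer(window),
         sigma = sigma, baseline_percentile = baseline_percentile,
         baseline_mode = baseline_mode, up_threshold = up_threshold,
         down_threshold = down_threshold, n_components = as.integer(n_components),
         false_label_fraction = false_label_fraction,
         filter_iterations = as.integer(filter_iterations),
         classifier = classifier, out_dir = out_dir),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be built with pipeline_config()", call. = FALSE)
  required <- c("seed", "sim", "window", "baseline_percentile", "baseline_mode",
                "up_threshold", "down_threshold", "n_components",
                "false_label_fraction", "filter_iterations", "classifier")
  for (f in required) {
    if (is.null(config[[f]]))
      stop("pipeline config is missing required field '", f, "'", call. = FALSE)
  }
  validate_sim_config(config$sim)
  if (config$window < 1L || config$window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  if (config$baseline_percentile <= 0 || config$baseline_percentile >= 100)
    stop("baseline_percentile must lie in (0, 100)", call. = FALSE)
  if (config$up_threshold <= config$down_threshold)
    stop("up_threshold must exceed down_threshold", call. = FALSE)
  if (config$false_label_fraction < 0 || config$false_label_fraction >= 1)
    stop("false_label_fraction must lie in [0, 1)", call. = FALSE)
  for (f in c("size", "decay", "maxit")) {
    if (is.null(config$classifier[[f]]))
      stop("classifier settings are missing required field '", f, "'", call. = FALSE)
  }
  invisible(config)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full classification workflow
#'
#' Executes simulate (or load) -> preprocessing + feature extraction ->
#' per-feature AUC screen -> leave-one-subject-out cross-validation with
#' false-label filtering, PCA, and classifier training per fold -> group
#' evaluation of the predicted pain values. With `out_dir` set, writes
#' `features.csv`, `auc_table.csv`, `fold_results.csv`,
#' `removal_log.csv`, and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional `calcium_cohort`; default generates one from
#'   `config$sim`.
#' @return Invisibly, a list with `features`, `auc_table`, `fold_results`,
#'   `removal_log`, `evaluations`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  validate_pipeline_config(config)
  cohort <- cohort %||% run_stage("simulate", generate_cohort(config$sim))
  features <- run_stage("features", cohort_features(
    cohort, window = config$window, sigma = config$sigma,
    baseline_percentile = config$baseline_percentile,
    baseline_mode = config$baseline_mode,
    up_threshold = config$up_threshold,
    down_threshold = config$down_threshold))
  auc_table <- run_stage("auc-table", build_auc_table(features))
  fold_results <- run_stage("loso", loso_cv(
    features, seed = make_seed(config$seed, 101L),
    false_label_fraction = config$false_label_fraction,
    filter_iterations = config$filter_iterations,
    n_components = config$n_components,
    size = config$classifier$size, decay = config$classifier$decay,
    maxit = config$classifier$maxit))
  removal_parts <- Filter(Negate(is.null),
    lapply(attr(fold_results, "folds"), function(f)
      if (nrow(f$removed)) cbind(fold_subject = f$subject, f$removed)))
  removal_log <- if (length(removal_parts)) {
    rl <- do.call(rbind, removal_parts)
    rownames(rl) <- NULL
    rl
  }
  evaluations <- run_stage("evaluate", list(
    pain_vs_nonpain = with(
      fold_results[fold_results$class != "analgesic", ],
      evaluate_groups(predicted_pain_value, class, positive = "pain")),
    pain_vs_analgesic = with(
      fold_results[fold_results$class != "non-pain", ],
      evaluate_groups(predicted_pain_value, class, positive = "pain")),
    pain_vs_rest = evaluate_groups(
      fold_results$predicted_pain_value,
      ifelse(fold_results$class == "pain", "pain", "rest"),
      positive = "pain")))
  manifest <- list(package = "painstate",
                   version = as.character(utils::packageVersion("painstate")),
                   seed = config$seed,
                   n_sessions = nrow(features),
                   n_subjects = length(unique(features$subject_id)),
                   config = c(serialize_pipeline_config(config)))
  bundle <- list(features = features, auc_table = auc_table,
                 fold_results = fold_results, removal_log = removal_log,
                 evaluations = evaluations, manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

serialize_pipeline_config <- function(config) {
  x <- unclass(config)
  x$sim <- serialize_config(config$sim)
  x
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(bundle$features, file.path(out_dir, "features.csv"))
  data.table::fwrite(bundle$auc_table, file.path(out_dir, "auc_table.csv"))
  fr <- bundle$fold_results
  attr(fr, "folds") <- NULL
  data.table::fwrite(as.data.frame(fr), file.path(out_dir, "fold_results.csv"))
  if (!is.null(bundle$removal_log) && nrow(bundle$removal_log))
    data.table::fwrite(bundle$removal_log, file.path(out_dir, "removal_log.csv"))
  write_json_file(bundle$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
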