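# deterministic per-stage seed derived from the master seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 131L + h) %% .Machine$integer.max
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end run, with the defaults used throughout:
#' 64 gray levels, CCC >= 0.9 capped at 100 features, correlation-distance
#' redundancy threshold 0.05, cumulative contribution weight 0.80,
#' 10-repeat stratified 10-fold cross-validation, Youden cut-off.
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param n_levels gray levels for texture quantization.
#' @param ccc_threshold,ccc_cap reproducibility-filter parameters.
#' @param distance_threshold redundancy-filter correlation distance.
#' @param stop cumulative contribution-weight stop threshold.
#' @param n_repeats,n_folds cross-validation plan.
#' @param output_dir artifact directory (`NULL` = no files written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_levels = 64L,
                            ccc_threshold = 0.9, ccc_cap = 100L,
                            distance_threshold = 0.05, stop = 0.80,
                            n_repeats = 10L, n_folds = 10L,
                            output_dir = NULL) {
  stopifnot(ccc_threshold >= -1, ccc_threshold <= 1,
            distance_threshold >= 0, distance_threshold <= 1,
            stop > 0, stop <= 1)
  structure(list(seed = as.integer(seed), n_levels = as.integer(n_levels),
                 ccc_threshold = ccc_threshold, ccc_cap = as.integer(ccc_cap),
                 distance_threshold = distance_threshold, stop = stop,
                 n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

config_hash <- function(config) {
  config <- config[setdiff(names(config), "output_dir")]  # not semantic
  s <- paste(vapply(config[order(names(config))],
                    function(v) paste(format(v), collapse = ","),
                    character(1)), collapse = "|")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)))
}

#' Run the full radiomics signature pipeline
#'
#' Stages, in order: feature extraction from the image cohort (or a
#' feature table taken as-is), reproducibility filtering against the
#' perturbed-replicate extraction (when replicates are given), redundancy
#' pruning, SVM-RFE selection, RBF-SVM training with repeated stratified
#' cross-validation, sigmoid signature, ROC cut-off, risk stratification
#' and evaluation. When `config$output_dir` is set, the artifacts
#' (features CSV, selection report JSON, predictions CSV, evaluation
#' JSON, log) are written there, each stamped with the config hash and
#' seed.
#'
#' @param config a [pipeline_config()].
#' @param vois optional list of [voi()] objects (image route).
#' @param labels class labels, one per VOI (image route).
#' @param replicate_vois optional list of perturbed re-segmentations
#'   paired with `vois`, for the CCC stage.
#' @param feature_table optional precomputed table with `case_id`,
#'   `label` and feature columns (table route; overrides `vois`).
#' @param replicate_table optional replicate feature table (CCC stage on
#'   the table route).
#' @return A list of class `pipeline_result`: `features`, `selection`,
#'   `cv`, `cutoff`, `risk`, `evaluation`, `config`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), vois = NULL,
                         labels = NULL, replicate_vois = NULL,
                         feature_table = NULL, replicate_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  hash <- config_hash(config)
  say("pipeline start: config %s, seed %d", hash, config$seed)

  qs <- quantization_spec(config$n_levels)
  if (is.null(feature_table)) {
    if (is.null(vois) || is.null(labels))
      stop("either a feature table or vois + labels are required")
    say("extracting %d features from %d cases", 308L, length(vois))
    feature_table <- extract_cohort(vois, labels, quantization = qs)
    if (!is.null(replicate_vois)) {
      say("extracting replicate features for reproducibility filtering")
      replicate_table <- extract_cohort(replicate_vois, labels,
                                        quantization = qs)
    }
  }
  feats <- setdiff(names(feature_table), c("case_id", "label"))
  feats <- feats[vapply(feature_table[feats], is.numeric, logical(1))]
  say("feature table: %d cases x %d features", nrow(feature_table),
      length(feats))
  # drop features undefined on any case (degenerate-VOI flags)
  ok <- vapply(feature_table[feats], function(v) !anyNA(v), logical(1))
  if (any(!ok)) say("dropping %d features with missing values", sum(!ok))
  feats <- feats[ok]

  ccc_values <- NULL
  if (!is.null(replicate_table)) {
    rf <- reproducibility_filter(feature_table, replicate_table,
                                 features = feats, cap = config$ccc_cap,
                                 threshold = config$ccc_threshold)
    ccc_values <- rf$ccc
    feats <- rf$kept
    say("reproducibility filter (CCC >= %.2f, cap %d): %d features kept",
        config$ccc_threshold, config$ccc_cap, length(feats))
  }

  kept <- redundancy_filter(feature_table, feats, ccc_values = ccc_values,
                            distance_threshold = config$distance_threshold)
  say("redundancy filter (distance < %.3f removed): %d features kept",
      config$distance_threshold, length(kept))

  ranking <- svm_rfe_rank(feature_table, feature_table$label, kept)
  sel <- cumulative_weight_select(ranking, stop = config$stop)
  say("SVM-RFE: %d features reach cumulative weight %.3f (stop %.2f)",
      length(sel$selected), sel$cumulative_weight, config$stop)
  selection <- structure(
    list(kept_after_ccc = feats, kept_after_redundancy = kept,
         rfe_ranking = ranking, selected = sel$selected,
         cumulative_weight = sel$cumulative_weight, ccc = ccc_values),
    class = "selection_report")

  plan <- cv_plan(n_repeats = config$n_repeats, n_folds = config$n_folds,
                  seed = stage_seed(config$seed, "crossval"))
  cv <- cross_validate(feature_table, plan = plan, features = kept,
                       select = TRUE, ccc_values = ccc_values,
                       distance_threshold = config$distance_threshold,
                       stop = config$stop)
  say("cross-validation: %d repeats x %d folds, %d prediction records",
      plan$n_repeats, plan$n_folds, nrow(cv$records))

  cut <- roc_cutoff(cv$case_pi$pi, cv$case_pi$label)
  say("ROC cut-off: Pi %.3f (decision %.3f), Youden %.3f",
      cut$pi_cutoff, cut$roc_cutoff, cut$youden)
  risk <- stratify_risk(cv$case_pi$pi, cut$pi_cutoff)
  eval <- evaluation_report(cv$case_pi$pi, cv$case_pi$label,
                            pi_cutoff = cut$pi_cutoff)
  say("evaluation: AUC %.3f, accuracy %.1f%%", eval$auc,
      eval$confusion$accuracy)

  result <- structure(
    list(features = feature_table, selection = selection, cv = cv,
         cutoff = cut, risk = risk, evaluation = eval, config = config,
         config_hash = hash, log = log),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    write_pipeline_artifacts(result, config$output_dir)
    say("artifacts written to %s", config$output_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = result$config_hash,
                seed = result$config$seed,
                catalog = "radvpi-308-v1")
  utils::write.csv(result$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(stamp, list(
      kept_after_ccc = result$selection$kept_after_ccc,
      kept_after_redundancy = result$selection$kept_after_redundancy,
      rfe_ranking = result$selection$rfe_ranking,
      selected = result$selection$selected,
      cumulative_weight = result$selection$cumulative_weight)),
    file.path(dir, "selection_report.json"), auto_unbox = TRUE,
    digits = NA)
  preds <- result$cv$records
  preds$risk_group <- as.character(
    stratify_risk(preds$pi, result$cutoff$pi_cutoff))
  utils::write.csv(preds, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  ev <- result$evaluation
  jsonlite::write_json(
    c(stamp, list(
      auc = ev$auc, auc_se = ev$auc_se, auc_ci = ev$auc_ci,
      pi_cutoff = result$cutoff$pi_cutoff,
      roc_cutoff = result$cutoff$roc_cutoff,
      confusion = ev$confusion, odds_ratio = ev$odds_ratio,
      or_p = ev$or_p, aic = ev$aic, pseudo_r2 = ev$pseudo_r2,
      concordance_index = ev$concordance_index,
      mann_whitney_p = ev$mann_whitney_p)),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("# config %s seed %d", result$config_hash,
                       result$config$seed), result$log),
             file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' One-command synthetic demonstration of the pipeline
#'
#' Generates a small synthetic image cohort with perturbed
#' re-segmentations, extracts the 308-feature catalog from both readings,
#' and runs the full selection / cross-validation / evaluation pipeline.
#'
#' @param seed master seed.
#' @param n_per_class phantoms per class (default 12, kept small so the
#'   demonstration runs in well under ten minutes).
#' @param output_dir optional artifact directory.
#' @return A `pipeline_result`.
#' @export
demo_pipeline <- function(seed = 1L, n_per_class = 12L,
                          output_dir = NULL) {
  ic <- image_cohort_spec(n_per_class = n_per_class,
                          seed = stage_seed(seed, "simulate"))
  cohort <- generate_image_cohort(ic)
  pspec_seed <- stage_seed(seed, "perturb")
  reps <- lapply(seq_along(cohort$vois), function(i)
    perturb_segmentation(cohort$vois[[i]],
                         perturbation_spec(boundary_shift = 1L,
                                           intensity_noise_sd = 10,
                                           seed = pspec_seed + i)))
  cfg <- pipeline_config(seed = seed, n_repeats = 2L,
                         n_folds = min(5L, n_per_class),
                         output_dir = output_dir)
  run_pipeline(cfg, vois = cohort$vois, labels = cohort$labels,
               replicate_vois = reps)
}
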