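#' Configuration for the end-to-end analysis pipeline
#'
#' Either `abundance_path`/`meta_path` point at input tables, or
#' `simulate` holds a [cohort_config()] and the cohort is generated. All
#' stochastic stages draw from streams derived from the single `seed`.
#'
#' @param seed integer master seed.
#' @param simulate a [cohort_config()] (used when no input paths given).
#' @param abundance_path,meta_path optional input files (TSV matrix, CSV
#'   metadata).
#' @param correction_mode see [correct_lfq()].
#' @param n_norm_proteins normalization proteins to select.
#' @param max_missing_fraction completeness filter threshold.
#' @param impute_k LLS neighbour count.
#' @param fc_thresh,p_thresh volcano thresholds.
#' @param selection list of [aucrf_select()] parameters.
#' @param model list of [train_panel_model()] parameters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, simulate = cohort_config(),
                            abundance_path = NULL, meta_path = NULL,
                            correction_mode = "both", n_norm_proteins = 6,
                            max_missing_fraction = 0.2, impute_k = 10,
                            fc_thresh = 0.5, p_thresh = 0.05,
                            selection = list(ntree_rank = 2000, mtry_rank = 8,
                                             cv_folds = 3, cv_repeats = 20,
                                             importance_threshold = 0.3),
                            model = list(ntree = 1000, mtry = 5, nodesize = 5,
                                         cost = 0.1052, cv_folds = 3,
                                         cv_repeats = 10)) {
  cfg <- list(seed = as.integer(seed), simulate = simulate,
              abundance_path = abundance_path, meta_path = meta_path,
              correction_mode = correction_mode,
              n_norm_proteins = n_norm_proteins,
              max_missing_fraction = max_missing_fraction,
              impute_k = impute_k, fc_thresh = fc_thresh,
              p_thresh = p_thresh, selection = selection, model = model)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the urinary-proteome prognostic pipeline end to end
#'
#' Executes the fixed stage order: correct -> select normalization
#' proteins -> NSF -> normalize -> completeness filter -> LLS imputation
#' -> differential screening -> univariate ROC -> AUC-based RF panel
#' selection -> RF and SVM panel models with 0-1 disease scores. Every
#' stage is logged with the stage tag of its input; a stage failure aborts
#' with the stage name and cause. Fully reproducible under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, all intermediate tables
#'   are written there (TSV/CSV/JSON).
#' @return a report list: `meta`, `baseline`, `normalization`,
#'   `n_filtered`, `differential`, `univariate`, `ranking`, `panel`,
#'   `models`, `scores`, `roc`, `log`, plus `truth` for simulated cohorts.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  for (p in c(config$abundance_path, config$meta_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("startup error: input path does not exist: ", p)
    }
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$abundance_path)) {
    raw <- run_stage("load", read_abundance_matrix(config$abundance_path))
    meta <- run_stage("load", read_sample_meta(config$meta_path))
    note("load: %d proteins x %d samples from %s",
         nrow(raw$values), ncol(raw$values), config$abundance_path)
  } else {
    sim <- config$simulate
    sim$seed <- config$seed
    cohort <- run_stage("simulate", generate_cohort(sim))
    raw <- cohort$abundance; meta <- cohort$meta; truth <- cohort$truth
    note("simulate: %d proteins x %d samples (seed %d)",
         nrow(raw$values), ncol(raw$values), config$seed)
  }
  meta <- meta_for(raw, meta)

  baseline <- run_stage("baseline", baseline_comparison(meta))
  note("baseline: %d variables, Bonferroni threshold %.5f",
       nrow(baseline$table), baseline$threshold)

  corrected <- run_stage("correct",
                         correct_lfq(raw, meta, mode = config$correction_mode))
  note("correct: stage %s -> %s (mode %s)", raw$stage, corrected$stage,
       config$correction_mode)

  nres <- run_stage("select_norm_proteins",
                    select_normalization_proteins(corrected, meta$group,
                                                  n_select = config$n_norm_proteins))
  nres <- run_stage("nsf", compute_nsf(corrected, nres))
  normalized <- run_stage("normalize", apply_nsf(corrected, nres))
  note("normalize: %d candidates, selected %s; NSF in [%.3f, %.3f]",
       length(nres$candidates), paste(nres$norm_protein_ids, collapse = ","),
       min(nres$nsf_by_sample), max(nres$nsf_by_sample))

  filtered <- run_stage("filter",
                        completeness_filter(normalized, meta$group,
                                            config$max_missing_fraction))
  note("filter: input stage %s; retained %d / removed %d proteins",
       normalized$stage, attr(filtered, "n_retained"), attr(filtered, "n_removed"))

  imputed <- run_stage("impute", suppressWarnings(
    lls_impute(filtered, k = config$impute_k)))
  note("impute: input stage %s; %d entries imputed", filtered$stage,
       sum(attr(imputed, "imputation_report")$n_imputed))

  diff_tab <- run_stage("differential",
                        differential_table(imputed, meta$group,
                                           fc_thresh = config$fc_thresh,
                                           p_thresh = config$p_thresh))
  cc <- attr(diff_tab, "class_counts")
  note("differential: input stage %s; up_PPG %d, down_PPG %d, ns %d",
       imputed$stage, cc[["up_PPG"]], cc[["down_PPG"]], cc[["ns"]])

  y <- log2(abundance_values(imputed))
  uni <- run_stage("univariate_roc", {
    data.frame(protein_id = rownames(y),
               auc = apply(y, 1, function(v) {
                 univariate_auc(v, meta$group)$auc
               }),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  note("univariate_roc: %d proteins, max AUC %.3f", nrow(uni), max(uni$auc))

  sel <- config$selection
  ranking <- run_stage("select_panel",
                       aucrf_select(t(y), meta$group,
                                    ntree_rank = sel$ntree_rank,
                                    mtry_rank = sel$mtry_rank,
                                    cv_folds = sel$cv_folds,
                                    cv_repeats = sel$cv_repeats,
                                    importance_threshold = sel$importance_threshold,
                                    seed = config$seed + 1L))
  panel <- filter_by_importance(ranking, sel$importance_threshold)
  note("select_panel: optimal set %d features (OOB AUC %.3f); panel: %s",
       attr(ranking, "opt_size"), attr(ranking, "opt_oob_auc"),
       paste(panel, collapse = ","))

  models <- scores <- roc <- NULL
  if (length(panel) >= 2) {
    mc <- config$model
    models <- list(
      rf = run_stage("train_rf",
                     train_panel_model(t(y), meta$group, "rf", features = panel,
                                       ntree = mc$ntree, mtry = mc$mtry,
                                       nodesize = mc$nodesize,
                                       cv_folds = mc$cv_folds,
                                       cv_repeats = mc$cv_repeats,
                                       seed = config$seed + 2L)),
      svm = run_stage("train_svm",
                      train_panel_model(t(y), meta$group, "svm", features = panel,
                                        cost = mc$cost, cv_folds = mc$cv_folds,
                                        cv_repeats = mc$cv_repeats,
                                        seed = config$seed + 3L)))
    scores <- lapply(models, predict_scores, x = t(y))
    roc <- lapply(scores, multivariate_roc, labels = meta$group)
    note("models: RF resub AUC %.3f (cv %.3f), SVM resub AUC %.3f (cv %.3f)",
         models$rf$resub_auc, models$rf$cv$cv_auc,
         models$svm$resub_auc, models$svm$cv$cv_auc)
  } else {
    note("models: skipped (panel has %d feature(s))", length(panel))
  }

  report <- list(meta = meta, baseline = baseline, corrected = corrected,
                 normalization = nres, normalized = normalized,
                 n_filtered = attr(filtered, "n_retained"),
                 imputed = imputed, differential = diff_tab,
                 univariate = uni, ranking = ranking, panel = panel,
                 models = models, scores = scores, roc = roc,
                 truth = truth, log = log)

  if (!is.null(outdir)) {
    write_abundance_matrix(corrected, file.path(outdir, "corrected.tsv"))
    write_abundance_matrix(normalized, file.path(outdir, "normalized.tsv"))
    write_abundance_matrix(imputed, file.path(outdir, "imputed.tsv"))
    write_sample_meta(meta, file.path(outdir, "sample_meta.csv"))
    utils::write.table(nres$stability_table,
                       file.path(outdir, "stability_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = names(nres$nsf_by_sample),
                                  nsf = nres$nsf_by_sample),
                       file.path(outdir, "nsf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff_tab, file.path(outdir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(ranking),
                       file.path(outdir, "panel_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(models)) {
      write_panel_model(models$rf, file.path(outdir, "model_rf.json"))
      write_panel_model(models$svm, file.path(outdir, "model_svm.json"))
      utils::write.table(data.frame(sample_id = names(scores$rf),
                                    rf = scores$rf, svm = scores$svm),
                         file.path(outdir, "scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(log, file.path(outdir, "pipeline_log.txt"))
  }
  report
}
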