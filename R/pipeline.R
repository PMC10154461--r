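#' Pipeline run configuration
#'
#' Bundles every stage's parameters at their protocol defaults: 3-mm
#' erosion, window/resampling/binning per [preprocess_config()], ICC
#' retention threshold 0.75, univariate alpha 0.05, RFE retention 30%,
#' tenfold 1-SE LASSO, 8:2 stratified split.
#'
#' @param phantom a [phantom_config()] (used when no manifest is given).
#' @param manifest optional path to a cohort manifest CSV; overrides the
#'   phantom generator as input source.
#' @param n_per_class phantom cases per class.
#' @param radius_mm erosion radius in mm.
#' @param preprocess a [preprocess_config()].
#' @param icc_threshold,icc_subset stability screening threshold and the
#'   number of cases re-featured from the second rater.
#' @param alpha,keep_frac,folds selection cascade parameters.
#' @param split_ratio training fraction.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(), manifest = NULL,
                       n_per_class = 60, radius_mm = 3.0,
                       preprocess = preprocess_config(),
                       icc_threshold = 0.75, icc_subset = 50,
                       alpha = 0.05, keep_frac = 0.30, folds = 10,
                       split_ratio = 0.8, seed = 1, out_dir = NULL) {
  structure(list(phantom = phantom, manifest = manifest,
                 n_per_class = n_per_class, radius_mm = radius_mm,
                 preprocess = preprocess, icc_threshold = icc_threshold,
                 icc_subset = icc_subset, alpha = alpha,
                 keep_frac = keep_frac, folds = folds,
                 split_ratio = split_ratio, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full radiomics pipeline
#'
#' Executes, for each of the four ROI methods on a shared cohort:
#' feature extraction, ICC stability screening against the second-rater
#' masks on a seeded case subset, the selection cascade on the training
#' split only, the logistic signature fit, scoring of both splits, and
#' the evaluation report. Cases with an empty derived or resampled ROI
#' are excluded jointly from all four methods so the paired comparisons
#' stay valid. With `out_dir` set, writes per-method feature tables,
#' selection traces and models, the evaluation report and a run
#' manifest with file hashes.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-generated `phantom_cohort` (otherwise one
#'   is generated from `config$phantom` with `config$seed`).
#' @return Object of class `pipeline_result`: `features` (per method),
#'   `icc` (per method `icc_report`), `traces`, `models`, `scores`,
#'   `split`, `report`, `excluded`, `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  cases <- if (!is.null(config$manifest)) load_manifest(config$manifest)
  else {
    if (is.null(cohort))
      cohort <- generate_cohort(config$phantom, config$n_per_class, config$seed)
    cohort$cases
  }
  feats <- extract_cohort_features(cases, config$radius_mm, config$preprocess,
                                   rater = 1)
  excluded <- attr(feats, "excluded")
  kept_ids <- unique(feats$case_id)
  if (length(kept_ids) < 10)
    .stop2("rimshrink_data_error", "fewer than 10 usable cases (",
           length(kept_ids), ")")

  # seeded second-rater subset for stability screening
  with_r2 <- kept_ids[vapply(cases[match(kept_ids, vapply(cases, `[[`, "", "case_id"))],
                             function(cs) !is.null(cs$mask_rater2), logical(1))]
  set.seed(config$seed + 1L)
  sub_ids <- if (length(with_r2) > config$icc_subset)
    sort(sample(with_r2, config$icc_subset)) else with_r2
  feats2 <- if (length(sub_ids) >= 3) {
    sub_cases <- cases[match(sub_ids, vapply(cases, `[[`, "", "case_id"))]
    extract_cohort_features(sub_cases, config$radius_mm, config$preprocess,
                            rater = 2)
  } else NULL

  reg <- feature_registry()$name
  per_method <- list()
  icc_reports <- list()
  traces <- list()
  models <- list()
  labels_of <- function(tab) tab$label[match(kept_ids, tab$case_id)]
  split <- NULL
  scores <- list(train = list(), val = list())
  for (m in .roi_methods) {
    tab <- feats[feats$roi_method == m, , drop = FALSE]
    tab <- tab[match(kept_ids, tab$case_id), , drop = FALSE]
    labels <- tab$label
    if (is.null(split))
      split <- split_train_val(labels, config$split_ratio, config$seed)
    icc_reports[[m]] <- if (!is.null(feats2))
      stability_filter(tab, feats2[feats2$roi_method == m, , drop = FALSE],
                       config$icc_threshold) else NULL
    xtr <- tab[split$train, reg, drop = FALSE]
    ytr <- labels[split$train]
    tr <- selection_cascade(xtr, ytr, icc_reports[[m]], config$alpha,
                            config$keep_frac, config$folds, config$seed)
    final <- if (length(tr$lasso)) tr$lasso else tr$rfe
    mod <- radiomics_signature(xtr, ytr, final)
    traces[[m]] <- tr
    models[[m]] <- mod
    scores$train[[m]] <- predict(mod, tab[split$train, reg, drop = FALSE])
    scores$val[[m]] <- predict(mod, tab[split$val, reg, drop = FALSE])
    per_method[[m]] <- tab
  }
  labels <- per_method[[1]]$label
  report <- eval_report(scores,
                        list(train = labels[split$train], val = labels[split$val]),
                        boot = 200, seed = config$seed)
  res <- structure(list(features = per_method, icc = icc_reports,
                        traces = traces, models = models, scores = scores,
                        split = split, report = report, excluded = excluded,
                        icc_subset_ids = sub_ids, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cases (%d excluded), %d-case ICC subset\n",
              nrow(x$features[[1]]), length(x$excluded), length(x$icc_subset_ids)))
  print(x$report)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (m in .roi_methods) {
    f <- file.path(out_dir, paste0("features_", m, ".csv"))
    write_feature_table(res$features[[m]], f)
    files <- c(files, f)
    f <- file.path(out_dir, paste0("trace_", m, ".json"))
    tr <- res$traces[[m]]
    jsonlite::write_json(list(stable = tr$stable, univariate = tr$univariate,
                              rfe = tr$rfe, lasso = tr$lasso,
                              lambda = tr$lasso_detail$lambda,
                              coefficients = as.list(tr$lasso_detail$coefficients)),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    f <- file.path(out_dir, paste0("model_", m, ".json"))
    write_signature_json(res$models[[m]], f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "eval_report.json")
  jsonlite::write_json(list(metrics = res$report$metrics,
                            mcnemar = lapply(res$report$mcnemar, as.data.frame),
                            pairwise = res$report$pairwise),
                       f, digits = NA)
  files <- c(files, f)
  cfg <- res$config
  cfg$phantom <- unclass(cfg$phantom)
  cfg$preprocess <- unclass(cfg$preprocess)
  manifest <- list(package_version = as.character(utils::packageVersion("rimshrink")),
                   seed = res$config$seed,
                   rng = res$config$phantom$rng,
                   config = unclass(cfg),
                   excluded_cases = res$excluded,
                   icc_subset = res$icc_subset_ids,
                   file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Rank the four ROI methods
#'
#' Ranks the methods by hold-out AUC and by hold-out pAUC and names the
#' winner under each criterion.
#'
#' @param result a `pipeline_result` (or an `eval_report`).
#' @param split which split to rank on (default `"val"`).
#' @return List of class `method_ranking`: `by_auc`, `by_pauc` (data
#'   frames sorted best-first), `winner_auc`, `winner_pauc`.
#' @export
compare_methods <- function(result, split = "val") {
  rep_ <- if (inherits(result, "pipeline_result")) result$report else result
  df <- rep_$metrics[rep_$metrics$split == split, , drop = FALSE]
  if (nrow(df) == 0)
    .stop2("rimshrink_data_error", "no metrics for split '", split, "'")
  by_auc <- df[order(-df$auc), c("roi_method", "auc")]
  by_pauc <- df[order(-df$pauc), c("roi_method", "pauc")]
  structure(list(by_auc = by_auc, by_pauc = by_pauc,
                 winner_auc = by_auc$roi_method[1],
                 winner_pauc = by_pauc$roi_method[1], split = split),
            class = "method_ranking")
}

#' @exportS3Method base::print
print.method_ranking <- function(x, ...) {
  cat(sprintf("<method_ranking> split '%s'\n", x$split))
  cat(sprintf("  by AUC : %s (winner %s)\n",
              paste(sprintf("%s=%.3f", x$by_auc$roi_method, x$by_auc$auc),
                    collapse = " "), x$winner_auc))
  cat(sprintf("  by pAUC: %s (winner %s)\n",
              paste(sprintf("%s=%.4f", x$by_pauc$roi_method, x$by_pauc$pauc),
                    collapse = " "), x$winner_pauc))
  invisible(x)
}
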