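#' Pipeline configuration
#'
#' Bundles the per-stage configurations with the data split and explanation
#' settings. Unknown keys in `...` are rejected so config files fail fast.
#'
#' @param cohort A `cohort_config` (used when no feature table is given).
#' @param partition A `partition_config`.
#' @param scarf A `scarf_config`.
#' @param adjust_at_inference Apply the confounder adjustment at inference
#'   time too (default FALSE: deployed predictions use raw features).
#' @param test_fraction Fraction of patients held out for evaluation.
#' @param shap Named list of Kernel SHAP controls (`n_coalitions`,
#'   `background_size`).
#' @param seed Global seed; stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            partition = partition_config(),
                            scarf = scarf_config(),
                            adjust_at_inference = FALSE,
                            test_fraction = 0.2,
                            shap = list(n_coalitions = 600L,
                                        background_size = 50L),
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(partition, "partition_config"),
            inherits(scarf, "scarf_config"))
  if (!is_number(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must lie in (0, 1)")
  }
  unknown <- setdiff(names(shap), c("n_coalitions", "background_size"))
  if (length(unknown)) stopf("unknown shap settings: %s",
                             paste(unknown, collapse = ", "))
  cfg <- list(cohort = cohort, partition = partition, scarf = scarf,
              adjust_at_inference = isTRUE(adjust_at_inference),
              test_fraction = test_fraction, shap = shap,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Confusion-matrix classification metrics
#'
#' Specificity, sensitivity, positive predictive value, F1 and accuracy
#' with a 95 percent Wilson interval, from raw confusion counts:
#' Sp = TN/(TN+FP), Se = TP/(TP+FN), PPV = TP/(TP+FP),
#' F1 = TP/(TP + (FP+FN)/2). Undefined ratios (0/0) are NA, not 0.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return data.frame with the counts and the derived metrics.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  n <- tp + fp + fn + tn
  ci <- wilson_ci(tp + tn, n)
  data.frame(
    tp = tp, fp = fp, fn = fn, tn = tn,
    ppv = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    f1 = ratio(tp, tp + 0.5 * (fp + fn)),
    accuracy = ratio(tp + tn, n),
    acc_ci_low = ci[1], acc_ci_high = ci[2]
  )
}

# evaluation report for predictions vs per-region truth
evaluation_report <- function(pred, truth_meta) {
  rows <- list()
  y_global <- truth_meta$label_basal | truth_meta$label_mid |
    truth_meta$label_apical
  for (region in c(scar_regions(), "global")) {
    if (region == "global") {
      y <- y_global == 1
      p <- pred$pred_global == 1
    } else {
      y <- truth_meta[[paste0("label_", region)]] == 1
      p <- pred[[paste0("pred_", region)]] == 1
    }
    m <- confusion_metrics(sum(p & y), sum(p & !y), sum(!p & y), sum(!p & !y))
    rows[[region]] <- cbind(region = region, m)
  }
  do.call(rbind, rows)
}

#' Train the full pipeline on a (generated or supplied) cohort
#'
#' Runs the training stages in order: feature table (generated from the
#' cohort config unless supplied), patient-level train/holdout split,
#' confounder adjustment fitted on the training patients and applied in
#' train mode, per-region recursive partitioning on patient-mean adjusted
#' features, and per-group encoder pretraining plus head fine-tuning.
#' Held-out ECGs are then predicted from raw (unadjusted) features and
#' scored.
#'
#' @param config A `pipeline_config`.
#' @param cohort Optional `ecg_cohort` (features + meta); generated from
#'   `config$cohort` when NULL.
#' @return List of class `scar_pipeline`: `bundle` (adjusters, partitions,
#'   models, config, registry hash, split), `report` (held-out
#'   `evaluation_report`), `predictions` (held-out predictions), `cohort`.
#' @export
run_train <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  meta <- cohort$meta
  need <- c("patient_id", "lvmi", "age", "sex",
            paste0("label_", scar_regions()))
  if (!all(need %in% names(meta))) {
    stopf("cohort meta lacks columns: %s",
          paste(setdiff(need, names(meta)), collapse = ", "))
  }
  pids <- unique(meta$patient_id)
  ho_pat <- with_seed(child_seed(config$seed, "split"),
                      sample(pids, round(config$test_fraction * length(pids))))
  tr <- !(meta$patient_id %in% ho_pat)

  adj <- fit_adjusters(cohort$features[tr, , drop = FALSE], meta[tr, ])
  Ftr <- apply_adjustment(adj, cohort$features[tr, , drop = FALSE],
                          meta[tr, ], mode = "train")

  ag <- aggregate_patients(Ftr, meta[tr, ])
  partitions <- list()
  for (region in scar_regions()) {
    pcfg <- config$partition
    pcfg$seed <- child_seed(config$seed, paste0("part_", region))
    partitions[[region]] <- recursive_partition(
      ag$X, ag$meta[[paste0("label_", region)]], pcfg)
  }

  scfg <- config$scarf
  scfg$seed <- child_seed(config$seed, "scarf")
  models <- train_regional_models(partitions, Ftr, meta[tr, ], scfg)

  X_ho <- cohort$features[!tr, , drop = FALSE]
  if (config$adjust_at_inference) {
    X_ho <- apply_adjustment(adj, X_ho, meta[!tr, ], mode = "train")
  }
  pred <- predict_scar(models, partitions, X_ho)
  report <- evaluation_report(pred, meta[!tr, ])

  out <- list(
    bundle = list(adjusters = adj, partitions = partitions, models = models,
                  config = config, registry_hash = registry_hash(),
                  holdout_patients = ho_pat),
    report = report,
    predictions = pred,
    cohort = cohort,
    train_rows = which(tr),
    train_features_adjusted = Ftr
  )
  class(out) <- "scar_pipeline"
  out
}

#' @export
print.scar_pipeline <- function(x, ...) {
  cat("scar_pipeline (trained)\n")
  rep <- x$report
  for (i in seq_len(nrow(rep))) {
    cat(sprintf("  %-7s F1 %.3f  Se %.3f  Sp %.3f  PPV %.3f\n",
                rep$region[i], rep$f1[i], rep$sensitivity[i],
                rep$specificity[i], rep$ppv[i]))
  }
  invisible(x)
}

#' Predict scar for new ECGs from a trained bundle
#'
#' Checks that the bundle's feature registry matches the installed one,
#' then routes and predicts each row from raw features (no adjustment, per
#' the training-only confounder-adjustment contract). An empty input yields
#' an empty prediction frame.
#'
#' @param bundle The `bundle` element of a `scar_pipeline` (or the pipeline
#'   itself).
#' @param X Feature matrix / data.frame with the 276 registry columns.
#' @param explain If TRUE, also compute Kernel SHAP explanations per region.
#' @param background Optional explanation background (defaults to the
#'   bundle's adjusted training features if present).
#' @return data.frame of predictions; with `explain = TRUE`, a list
#'   `(predictions, explanations)`.
#' @export
run_predict <- function(bundle, X, explain = FALSE, background = NULL) {
  if (inherits(bundle, "scar_pipeline")) {
    if (is.null(background)) background <- bundle$train_features_adjusted
    bundle <- bundle$bundle
  }
  if (!identical(bundle$registry_hash, registry_hash())) {
    stopf("feature registry mismatch: bundle %s vs installed %s",
          bundle$registry_hash, registry_hash())
  }
  if (is.data.frame(X)) X <- as.matrix(X[, ecg_feature_names(), drop = FALSE])
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, ecg_feature_names()))
  if (nrow(X) == 0L) {
    empty <- data.frame()
    return(if (explain) list(predictions = empty, explanations = list())
           else empty)
  }
  pred <- predict_scar(bundle$models, bundle$partitions, X)
  if (!explain) return(pred)
  if (is.null(background)) stopf("explanations need a background matrix")
  shap_cfg <- bundle$config$shap
  expl <- explain_scar(bundle$models, bundle$partitions, X, background,
                       n_coalitions = shap_cfg$n_coalitions,
                       background_size = shap_cfg$background_size,
                       seed = child_seed(bundle$config$seed, "shap"))
  list(predictions = pred, explanations = expl)
}

#' Ablation study: full pipeline vs no-self-supervised vs no-partitioning
#'
#' Trains and evaluates the three pipeline variants on identical cohorts
#' and splits, over one or more cohort seeds, and reports the held-out
#' global F1 of each arm (per seed and mean). The `no_self_supervised` arm
#' skips contrastive pretraining; the `no_partitioning` arm places all
#' patients in a single group.
#'
#' @param config A `pipeline_config` describing the common conditions.
#' @param seeds Integer vector of cohort/split seeds.
#' @return data.frame with one row per (seed, arm) plus the mean rows.
#' @export
run_ablation_study <- function(config = pipeline_config(), seeds = c(1L, 2L, 3L)) {
  res <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    cfg$cohort$seed <- child_seed(seed, "cohort")
    cohort <- generate_cohort(cfg$cohort)
    for (arm in c("full", "no_self_supervised", "no_partitioning")) {
      acfg <- cfg
      if (arm == "no_self_supervised") acfg$scarf$no_self_supervised <- TRUE
      if (arm == "no_partitioning") acfg$partition$no_partitioning <- TRUE
      fit <- run_train(acfg, cohort = cohort)
      g <- fit$report[fit$report$region == "global", ]
      res[[length(res) + 1L]] <- data.frame(seed = seed, arm = arm,
                                            f1_global = g$f1)
    }
  }
  df <- do.call(rbind, res)
  means <- stats::aggregate(f1_global ~ arm, df, mean)
  means <- data.frame(seed = NA_integer_, arm = means$arm,
                      f1_global = means$f1_global)
  rbind(df, means)
}
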