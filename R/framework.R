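#' Framework configuration
#'
#' Defaults follow the shipped protocol: 25% of the cohort held out as the
#' final test set, 1000 bootstrap replicates for the stability screen,
#' marginal significance level 0.1, 5 cross-validation folds, and a 0.5
#' classification threshold.
#'
#' @param test_fraction held-out test proportion.
#' @param B bootstrap replicate count for the stability screen.
#' @param alpha significance level of the robustness gate.
#' @param strategy robustness decision rule, `"pooled"` or `"consensus"`.
#' @param k_folds cross-validation folds per stage.
#' @param threshold classification threshold for the confusion-matrix
#'   metrics.
#' @param seed master seed; fans out to named sub-seeds for the split, the
#'   bootstrap, and each model fit.
#' @param hyperparameters see [default_hyperparameters()].
#' @param estimator attribution estimator used inside the bootstrap screen.
#' @param confirm `"flagged"` (exclude every counterintuitive-flagged
#'   variable, mirroring a review board that upholds all flags), `"none"`,
#'   or an explicit character vector of confirmed exclusions.
#' @param stratify stratify the holdout split by label.
#' @param do_cv run per-stage cross-validation (the validation column of the
#'   metric table).
#' @param delta_p_values intervention values used for the counterfactual
#'   audit of flagged binary variables.
#' @return A `framework_config` list.
#' @export
framework_config <- function(test_fraction = 0.25, B = 1000L, alpha = 0.1,
                             strategy = "pooled", k_folds = 5L,
                             threshold = 0.5, seed = 1L,
                             hyperparameters = default_hyperparameters(),
                             estimator = "tree_path",
                             confirm = "flagged",
                             stratify = TRUE, do_cv = TRUE,
                             delta_p_values = c(0, 1)) {
  assert_that(B >= 2, "config_error", "B must be at least 2")
  assert_that(test_fraction > 0 && test_fraction < 1, "config_error",
              "test_fraction must be in (0, 1)")
  assert_that(alpha > 0 && alpha < 1, "config_error",
              "alpha must be in (0, 1)")
  assert_that(k_folds >= 2, "config_error", "k_folds must be at least 2")
  structure(list(test_fraction = test_fraction, B = as.integer(B),
                 alpha = alpha, strategy = strategy,
                 k_folds = as.integer(k_folds), threshold = threshold,
                 seed = as.integer(seed), hyperparameters = hyperparameters,
                 estimator = estimator, confirm = confirm,
                 stratify = stratify, do_cv = do_cv,
                 delta_p_values = delta_p_values),
            class = "framework_config")
}

fit_stage <- function(dev, test, variables, config, seed) {
  dev_s <- subset_cohort(dev, vars = variables)
  test_s <- subset_cohort(test, vars = variables)
  dev_imp <- impute_train_mean(dev_s)
  test_imp <- impute_train_mean(dev_s, test_s)
  model <- fit_gbm(dev_imp$X, dev_imp$y, config$hyperparameters, seed = seed)
  metrics <- list(
    train = compute_metrics(dev_imp$y, predict_risk(model, dev_imp$X),
                            config$threshold),
    test = compute_metrics(test_imp$y, predict_risk(model, test_imp$X),
                           config$threshold))
  cv <- NULL
  if (isTRUE(config$do_cv)) {
    cv <- cross_validate(dev_s, config$k_folds, config$hyperparameters,
                         seed = seed, threshold = config$threshold)
    metrics$validation <- cv$validation
  }
  list(variables = variables, model = model, metrics = metrics, cv = cv,
       column_means = attr(dev_imp, "column_means"))
}

#' Run the full expert-guided modelling framework
#'
#' Executes the three-stage protocol end to end:
#' \enumerate{
#'   \item hold out the test fraction; fit and evaluate the model on
#'     \emph{all} candidate variables;
#'   \item bootstrap stability screen on the development rows only; keep the
#'     robust variables; refit and evaluate;
#'   \item audit the robust variables against the declared expectations,
#'     run the counterfactual delta-p probe for flagged binary variables on
#'     the test rows, exclude the confirmed counterintuitive variables, and
#'     fit the final intelligible model.
#' }
#' The test rows are scored once per stage and are never consulted by the
#' selection steps. The result records, per stage, the variables, the fitted
#' model, and train/validation/test metrics.
#'
#' @param cohort a [cohort()].
#' @param expectations a [direction_expectations()] (may be empty:
#'   no variable is then ever flagged).
#' @param config a [framework_config()].
#' @return A `framework_result`.
#' @export
run_framework <- function(cohort,
                          expectations = direction_expectations(character(0),
                                                                character(0)),
                          config = framework_config()) {
  seeds <- derive_seeds(config$seed, 6L)
  split <- holdout_split(cohort, config$test_fraction, seed = seeds[1],
                         stratify = config$stratify)
  dev <- subset_cohort(cohort, rows = split$dev_indices)
  test <- subset_cohort(cohort, rows = split$test_indices)

  log <- list()
  note <- function(variable, stage, evidence, action) {
    log[[length(log) + 1L]] <<- data.frame(
      variable = variable, stage = stage, evidence = evidence,
      action = action, stringsAsFactors = FALSE)
  }

  # Stage 1: all candidate variables
  stage_all <- fit_stage(dev, test, colnames(cohort$X), config, seeds[2])

  # Step 1: bootstrap stability screen (development rows only)
  stability <- bootstrap_stability(dev, B = config$B,
                                   hyperparameters = config$hyperparameters,
                                   seed = seeds[3],
                                   estimator = config$estimator)
  robust <- select_robust(stability, config$alpha, config$strategy)
  assert_that(length(robust) >= 1, "selection_error",
              "no variable passed the robustness screen")
  for (v in stability$variables) {
    kr <- stability$pooled[[v]]
    note(v, "stability",
         sprintf("pooled tau %.3f, p %.3g", kr$tau_b, kr$p_value),
         if (v %in% robust) "selected" else "excluded (non-robust)")
  }
  stage_robust <- fit_stage(dev, test, robust, config, seeds[4])

  # Step 2: knowledge audit on the robust set
  audit <- flag_counterintuitive(stability, expectations, robust = robust)
  binary_vars <- cohort$schema$name[cohort$schema$vtype == "binary"]
  test_imp <- impute_train_mean(subset_cohort(dev, vars = robust),
                                subset_cohort(test, vars = robust))
  for (v in intersect(audit$flagged, binary_vars)) {
    audit$delta_p[[v]] <- counterfactual_delta(
      stage_robust$model, test_imp$X, v,
      v0 = config$delta_p_values[1], v1 = config$delta_p_values[2])
  }
  confirm <- if (identical(config$confirm, "flagged")) audit$flagged
             else if (identical(config$confirm, "none")) character(0)
             else config$confirm
  intelligible <- finalize_variables(audit, confirm_exclusions = confirm)
  for (v in robust) {
    fl <- audit$table$flag[audit$table$variable == v]
    note(v, "audit", sprintf("flag: %s", fl),
         if (v %in% intelligible) "retained" else "excluded (confirmed)")
  }
  stage_final <- fit_stage(dev, test, intelligible, config, seeds[5])

  structure(list(stages = list(all = stage_all, robust = stage_robust,
                               intelligible = stage_final),
                 stability = stability, audit = audit,
                 variables = list(all = colnames(cohort$X), robust = robust,
                                  intelligible = intelligible),
                 split = split, config = config,
                 decision_log = do.call(rbind, log)),
            class = "framework_result")
}

#' @export
print.framework_result <- function(x, ...) {
  nv <- vapply(x$variables, length, 0L)
  cat(sprintf("<framework_result> variables: %d all -> %d robust -> %d intelligible\n",
              nv[["all"]], nv[["robust"]], nv[["intelligible"]]))
  cat(sprintf("  flagged counterintuitive: %s\n",
              if (length(x$audit$flagged)) paste(x$audit$flagged, collapse = ", ")
              else "(none)"))
  for (st in names(x$stages)) {
    m <- x$stages[[st]]$metrics
    cat(sprintf("  %-12s train AUC %.4f | test AUC %.4f | test acc %.4f\n",
                st, m$train$auc, m$test$auc, m$test$accuracy))
  }
  invisible(x)
}

#' @export
summary.framework_result <- function(object, ...) {
  out <- metrics_table(object)
  cat("Three-stage metric table (rows: stage x split):\n")
  print(out, digits = 4)
  invisible(out)
}

#' Tabulate the three-stage metrics
#'
#' One row per stage and data split (training / validation / test) with the
#' six metrics; validation rows carry the cross-validation mean with the SD
#' over folds in companion columns.
#'
#' @param result a `framework_result`.
#' @return A data frame.
#' @export
metrics_table <- function(result) {
  one_row <- function(stage, split, values, sds = NULL) {
    row <- data.frame(stage = stage, split = split,
                      t(vapply(metric_names, function(mm)
                        values[[mm]] %||% NA_real_, 0.0)),
                      stringsAsFactors = FALSE)
    for (mm in metric_names) {
      row[[paste0(mm, "_sd")]] <- if (is.null(sds)) NA_real_ else
        sds[[mm]] %||% NA_real_
    }
    row
  }
  rows <- list()
  for (st in names(result$stages)) {
    m <- result$stages[[st]]$metrics
    rows[[length(rows) + 1L]] <- one_row(st, "training", m$train)
    if (!is.null(m$validation)) {
      rows[[length(rows) + 1L]] <- one_row(st, "validation",
                                           m$validation$mean,
                                           m$validation$sd)
    }
    rows[[length(rows) + 1L]] <- one_row(st, "test", m$test)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
predict.framework_result <- function(object, newdata, stage = "intelligible",
                                     ...) {
  st <- object$stages[[stage]]
  X <- as.matrix(newdata)[, st$variables, drop = FALSE]
  # apply the stage's stored training means to any missing cells
  mu <- st$column_means
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mu[colnames(X)[j]]
  }
  predict_risk(st$model, X)
}
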