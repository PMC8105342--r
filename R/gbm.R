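#' Default gradient-boosting hyperparameters
#'
#' Fixed, documented defaults used throughout the package: shallow trees with
#' conservative shrinkage and a minimum child weight large enough to keep
#' idiosyncratic splits in check on cohorts of a few hundred patients. They
#' were tuned once on synthetic cohorts and are deterministic (no row or
#' column subsampling), so a fit depends only on the data and the seed.
#'
#' @param nrounds boosting rounds.
#' @param max_depth tree depth.
#' @param eta learning rate.
#' @param min_child_weight minimum hessian weight per leaf.
#' @param lambda L2 regularization on leaf values.
#' @param scale_pos_weight class weight for the unfavorable class; 1 (no
#'   reweighting) by default.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(nrounds = 80L, max_depth = 3L, eta = 0.1,
                                    min_child_weight = 8, lambda = 1,
                                    scale_pos_weight = 1) {
  list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
       eta = eta, min_child_weight = min_child_weight, lambda = lambda,
       subsample = 1, colsample_bytree = 1,
       scale_pos_weight = scale_pos_weight)
}

#' Fit the gradient-boosted risk model
#'
#' Trains a tree-ensemble classifier (XGBoost, binary logistic objective) on
#' a complete feature matrix. The returned bundle stores the booster, the
#' feature names in training order, the training base rate (proportion of
#' unfavorable outcomes, the anchor from which per-patient attributions
#' deviate), the hyperparameters and the seed.
#'
#' @param train_X numeric matrix without missing values.
#' @param train_y 0/1 labels (1 = unfavorable), both classes present.
#' @param hyperparameters see [default_hyperparameters()].
#' @param seed integer seed; fits are deterministic given data and seed.
#' @return A `risk_model` object.
#' @export
fit_gbm <- function(train_X, train_y,
                    hyperparameters = default_hyperparameters(),
                    seed = 1L) {
  train_X <- as.matrix(train_X)
  assert_that(!anyNA(train_X), "fit_error",
              "training matrix contains missing values; impute first")
  train_y <- as.integer(train_y)
  assert_that(length(unique(train_y)) == 2, "fit_error",
              "training labels are single-class")
  assert_that(!is.null(colnames(train_X)), "fit_error",
              "training matrix must have column names")
  hp <- hyperparameters
  params <- c(list(objective = "binary:logistic", nthread = 1,
                   seed = as.integer(seed)),
              hp[setdiff(names(hp), "nrounds")])
  dtrain <- xgboost::xgb.DMatrix(train_X, label = train_y, nthread = 1)
  booster <- with_seed(seed, xgboost::xgb.train(
    params = params, data = dtrain, nrounds = hp$nrounds, verbose = 0))
  structure(list(booster = booster,
                 features = colnames(train_X),
                 base_rate = mean(train_y),
                 hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d features, %d rounds (depth %d, eta %.2f); training base rate %.3f\n",
              length(x$features), x$hyperparameters$nrounds,
              x$hyperparameters$max_depth, x$hyperparameters$eta,
              x$base_rate))
  invisible(x)
}

align_features <- function(model, X) {
  X <- as.matrix(X)
  assert_that(!is.null(colnames(X)), "feature_alignment_error",
              "matrix must carry column names")
  assert_that(setequal(colnames(X), model$features),
              "feature_alignment_error",
              "columns do not match the model's feature list")
  X[, model$features, drop = FALSE]
}

#' Predict unfavorable-outcome risk
#'
#' @param model a `risk_model`.
#' @param X complete feature matrix with the model's columns (any order).
#' @param output `"probability"` (default) or `"margin"` (log-odds).
#' @return Numeric vector, one risk score (P(unfavorable)) per row.
#' @export
predict_risk <- function(model, X, output = c("probability", "margin")) {
  output <- match.arg(output)
  X <- align_features(model, X)
  assert_that(!anyNA(X), "feature_alignment_error",
              "prediction matrix contains missing values; impute first")
  d <- xgboost::xgb.DMatrix(X, nthread = 1)
  as.numeric(predict(model$booster, d,
                     outputmargin = output == "margin"))
}

#' @export
predict.risk_model <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Classification and ranking metrics
#'
#' AUC is the rank-based (Mann-Whitney) probability that a random
#' unfavorable case is scored above a random favorable one, ties counted
#' half. The remaining metrics are computed from the confusion matrix at the
#' given threshold (predicted positive iff score >= threshold). When no
#' positives are predicted, precision (and hence F1) is undefined and
#' reported as `NA` with a warning.
#'
#' @param y_true 0/1 labels, both classes present.
#' @param scores risk scores.
#' @param threshold classification threshold, default 0.5.
#' @return A `metric_set` list: `auc`, `accuracy`, `f1`, `sensitivity`,
#'   `specificity`, `precision`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true)
  assert_that(length(y_true) == length(scores), "metric_error",
              "labels and scores differ in length")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  assert_that(n1 > 0 && n0 > 0, "metric_error",
              "AUC undefined for single-class labels")
  r <- rank(scores)  # midranks: ties counted half
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y_true == 1); fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1); tn <- sum(pred == 0 & y_true == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) {
    warning("no predicted positives; precision undefined")
    NA_real_
  } else tp / (tp + fp)
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  structure(list(auc = auc, accuracy = (tp + tn) / length(y_true), f1 = f1,
                 sensitivity = sens, specificity = spec, precision = prec,
                 threshold = threshold),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("AUC %.4f | acc %.4f | F1 %.4f | sens %.4f | spec %.4f | prec %.4f\n",
              x$auc, x$accuracy, x$f1, x$sensitivity, x$specificity,
              x$precision))
  invisible(x)
}

metric_names <- c("auc", "accuracy", "f1", "sensitivity", "specificity",
                  "precision")

stratified_folds <- function(y, k, seed) {
  assert_that(k >= 2, "fold_error", "k must be at least 2")
  assert_that(min(table(y)) >= k, "fold_error",
              "fold count exceeds minority-class count")
  with_seed(seed, {
    fold <- integer(length(y))
    start <- 0L
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- (start + seq_along(idx) - 1L) %% k + 1L
      start <- (start + length(idx)) %% k
    }
    fold
  })
}

#' Stratified k-fold cross-validation of the risk model
#'
#' Folds are stratified by label, disjoint and cover the development cohort.
#' Mean imputation is refit inside each training fold and applied to the
#' held-out fold, so no fold statistics leak.
#'
#' @param dev development [cohort()] (missing values allowed).
#' @param k fold count, default 5.
#' @param hyperparameters see [default_hyperparameters()].
#' @param seed integer seed.
#' @param threshold classification threshold.
#' @return A `cv_result` list: `folds` (per-fold train/validation
#'   `metric_set`s), `fold_assignment`, `mean` and `sd` (named lists over
#'   the six metrics, for train and validation).
#' @export
cross_validate <- function(dev, k = 5L,
                           hyperparameters = default_hyperparameters(),
                           seed = 1L, threshold = 0.5) {
  fold <- stratified_folds(dev$y, k, seed)
  seeds <- derive_seeds(seed, k)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- subset_cohort(dev, rows = which(fold != f))
    va <- subset_cohort(dev, rows = which(fold == f))
    tr_imp <- impute_train_mean(tr)
    va_imp <- impute_train_mean(tr, va)
    model <- fit_gbm(tr_imp$X, tr_imp$y, hyperparameters, seed = seeds[f])
    folds[[f]] <- list(
      train = compute_metrics(tr_imp$y, predict_risk(model, tr_imp$X),
                              threshold),
      validation = compute_metrics(va_imp$y, predict_risk(model, va_imp$X),
                                   threshold))
  }
  summarize <- function(side) {
    vals <- sapply(metric_names, function(m)
      vapply(folds, function(fd) fd[[side]][[m]], 0.0))
    list(mean = as.list(colMeans(vals)),
         sd = as.list(apply(vals, 2, stats::sd)))
  }
  structure(list(folds = folds, fold_assignment = fold, k = k,
                 train = summarize("train"),
                 validation = summarize("validation")),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", x$k))
  for (side in c("train", "validation")) {
    m <- x[[side]]
    cat(sprintf("  %-10s AUC %.4f (%.4f) acc %.4f (%.4f) F1 %.4f (%.4f)\n",
                side, m$mean$auc, m$sd$auc, m$mean$accuracy, m$sd$accuracy,
                m$mean$f1, m$sd$f1))
  }
  invisible(x)
}

#' Save / load a risk model
#'
#' The model is persisted as a single self-describing JSON file holding the
#' feature list, hyperparameters, base rate, seed, and the booster payload
#' (base64).
#'
#' @param model a `risk_model`.
#' @param path output path.
#' @return `path` invisibly for save; a `risk_model` for load.
#' @export
save_risk_model <- function(model, path) {
  payload <- list(
    features = model$features,
    base_rate = model$base_rate,
    hyperparameters = model$hyperparameters,
    seed = model$seed,
    booster_raw = jsonlite::base64_enc(
      as.raw(xgboost::xgb.save.raw(model$booster)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  booster <- xgboost::xgb.load.raw(
    jsonlite::base64_dec(payload$booster_raw))
  structure(list(booster = booster,
                 features = payload$features,
                 base_rate = payload$base_rate,
                 hyperparameters = as.list(payload$hyperparameters),
                 seed = as.integer(payload$seed)),
            class = "risk_model")
}
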