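#' Kendall tau-b with tie-corrected significance
#'
#' Rank correlation between a variable's values and its attribution values,
#' with tie corrections in both margins:
#' tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2)) where n0 = n(n-1)/2 and n1, n2
#' are the tied-pair counts of the two vectors. The two-sided p-value comes
#' from the tie-corrected normal approximation of the distribution of C - D
#' under the null. Computed in O(n log n), so pooled vectors spanning many
#' bootstrap replicates remain cheap.
#'
#' @param x value vector.
#' @param s contribution vector, same length, n >= 3.
#' @return A `kendall_result` list: `tau_b`, `p_value`, `n_pairs` (the
#'   sample size n).
#' @export
kendall_tau_b <- function(x, s) {
  assert_that(length(x) == length(s), "degenerate_input_error",
              "x and s must have equal length")
  assert_that(length(x) >= 3, "degenerate_input_error",
              "need at least 3 observations")
  ok <- !is.na(x) & !is.na(s)
  x <- x[ok]; s <- s[ok]
  assert_that(length(x) >= 3, "degenerate_input_error",
              "need at least 3 complete pairs")
  assert_that(length(unique(x)) > 1 && length(unique(s)) > 1,
              "degenerate_input_error",
              "constant vector: association not assessable")
  res <- kendall_tau_b_cpp(as.numeric(x), as.numeric(s))
  p <- if (is.na(res$z)) NA_real_ else 2 * stats::pnorm(-abs(res$z))
  structure(list(tau_b = res$tau_b, p_value = min(p, 1),
                 n_pairs = length(x)),
            class = "kendall_result")
}

#' @export
print.kendall_result <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.4f (two-sided p = %.3g, n = %d)\n",
              x$tau_b, x$p_value, x$n_pairs))
  invisible(x)
}

safe_kendall <- function(x, s) {
  tryCatch(kendall_tau_b(x, s),
           degenerate_input_error = function(e)
             structure(list(tau_b = NA_real_, p_value = NA_real_,
                            n_pairs = sum(!is.na(x) & !is.na(s))),
                       class = "kendall_result"))
}

#' Bootstrap stability of attribution behavior
#'
#' Step 1 of the intelligible variable selection. For each of `B` bootstrap
#' replicates: draw n development rows with replacement, mean-impute with
#' the replicate's own column means, fit the tree ensemble, and attribute
#' the predictions on a fixed evaluation set (the full development cohort,
#' imputed with the replicate's training means so nothing outside the
#' replicate leaks in). Per variable, the monotone association between its
#' values and its attributions is summarized with Kendall tau-b, both per
#' replicate and pooled over all replicates' (value, attribution) pairs.
#'
#' The pooled p-value is a screening score, not calibrated inference:
#' pooling concatenates dependent replicates and inflates the effective
#' sample size. The per-replicate results and the sign-consistency fraction
#' support the alternative consensus rule in [select_robust()].
#'
#' @param dev development [cohort()] (missing values allowed).
#' @param B bootstrap replicate count (>= 2); the shipped protocol default
#'   in [framework_config()] is 1000.
#' @param hyperparameters see [default_hyperparameters()].
#' @param seed master seed; per-replicate seeds are derived from it so any
#'   replicate is reproducible in isolation.
#' @param estimator attribution estimator passed to [explain()];
#'   `"tree_path"` (default) keeps B model explanations tractable.
#' @param output_space attribution space for the association; log-odds by
#'   default (the ensemble's additive space; tau is rank-based, so any
#'   monotone rescaling gives the same result up to the row-wise
#'   probability rescale).
#' @param max_retries redraws allowed for single-class replicates.
#' @return A `stability_report`: per-variable pooled `kendall_result`s,
#'   per-replicate tau/p matrices, sign-consistency fractions, `B`, and the
#'   evaluation row count.
#' @export
bootstrap_stability <- function(dev, B = 1000L,
                                hyperparameters = default_hyperparameters(),
                                seed = 1L,
                                estimator = c("tree_path", "interventional"),
                                output_space = "log_odds",
                                max_retries = 25L) {
  estimator <- match.arg(estimator)
  assert_that(B >= 2, "config_error", "B must be at least 2")
  assert_that(length(unique(dev$y)) == 2, "fit_error",
              "development cohort is single-class")
  n <- nrow(dev$X); d <- ncol(dev$X)
  vars <- colnames(dev$X)
  seeds <- derive_seeds(seed, B)

  tau_mat <- matrix(NA_real_, B, d, dimnames = list(NULL, vars))
  p_mat <- matrix(NA_real_, B, d, dimnames = list(NULL, vars))
  # pooled (value, contribution) pairs, accumulated per variable
  pool_x <- matrix(NA_real_, B * n, d)
  pool_s <- matrix(NA_real_, B * n, d)

  for (b in seq_len(B)) {
    rows <- NULL
    for (try in seq_len(max_retries)) {
      cand <- with_seed(seeds[b] + (try - 1L),
                        sample.int(n, n, replace = TRUE))
      if (length(unique(dev$y[cand])) == 2) { rows <- cand; break }
    }
    assert_that(!is.null(rows), "bootstrap_error",
                "could not draw a two-class replicate after %d tries",
                max_retries)
    boot <- subset_cohort(dev, rows = rows)
    boot_imp <- impute_train_mean(boot)
    eval_imp <- impute_train_mean(boot, dev)  # replicate statistics only
    model <- fit_gbm(boot_imp$X, boot_imp$y, hyperparameters,
                     seed = seeds[b])
    attr <- explain(model, eval_imp$X, background = boot_imp$X,
                    output_space = if (output_space == "log_odds")
                      "log_odds" else "probability",
                    estimator = estimator, seed = seeds[b])
    at <- (b - 1L) * n + seq_len(n)
    pool_x[at, ] <- eval_imp$X
    pool_s[at, ] <- attr$phi
    for (j in seq_len(d)) {
      kr <- safe_kendall(eval_imp$X[, j], attr$phi[, j])
      tau_mat[b, j] <- kr$tau_b
      p_mat[b, j] <- kr$p_value
    }
  }

  pooled <- lapply(seq_len(d), function(j)
    safe_kendall(pool_x[, j], pool_s[, j]))
  names(pooled) <- vars
  sign_consistency <- vapply(seq_len(d), function(j) {
    tj <- tau_mat[, j][!is.na(tau_mat[, j])]
    if (length(tj) == 0) return(0)
    max(mean(tj > 0), mean(tj < 0))
  }, 0.0)
  names(sign_consistency) <- vars
  # bootstrap sign test of the tau direction: the fraction of replicates
  # that do not support the dominant sign; replicates where the variable
  # was unused (degenerate tau) count against sign stability
  sign_p <- vapply(seq_len(d), function(j) {
    tj <- tau_mat[, j]
    frac_pos <- mean(!is.na(tj) & tj > 0)
    frac_neg <- mean(!is.na(tj) & tj < 0)
    1 - max(frac_pos, frac_neg)
  }, 0.0)
  names(sign_p) <- vars

  structure(list(B = as.integer(B), variables = vars,
                 pooled = pooled,
                 tau_replicates = tau_mat, p_replicates = p_mat,
                 sign_consistency = sign_consistency,
                 sign_p = sign_p,
                 n_eval = n, seed = as.integer(seed),
                 replicate_seeds = seeds,
                 estimator = estimator, output_space = output_space),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  df <- stability_summary(x)
  cat(sprintf("<stability_report> B = %d replicates over %d variables (n = %d)\n",
              x$B, length(x$variables), x$n_eval))
  print(utils::head(df[order(df$sign_p, -abs(df$pooled_tau)), ], 10))
  invisible(x)
}

#' Summarize a stability report as a table
#'
#' One row per variable: pooled tau, pooled p, sign-consistency, and the
#' robustness decision at the given significance level.
#'
#' @param report a `stability_report`.
#' @param alpha significance level used for the `robust` column.
#' @param strategy see [select_robust()].
#' @return A data frame.
#' @export
stability_summary <- function(report, alpha = 0.1, strategy = "pooled") {
  robust <- select_robust(report, alpha, strategy)
  data.frame(
    variable = report$variables,
    pooled_tau = vapply(report$pooled, `[[`, 0.0, "tau_b"),
    pooled_p = vapply(report$pooled, `[[`, 0.0, "p_value"),
    sign_p = unname(report$sign_p),
    sign_consistency = unname(report$sign_consistency),
    robust = report$variables %in% robust,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Select variables with robust attribution behavior
#'
#' A variable is robust when its monotone association with its own
#' attributions is significant, either positive or negative, at `alpha`
#' (default 0.1, the marginal-significance screen of the shipped protocol)
#' \emph{with respect to bootstrap resampling of the training set}.
#'
#' Pooled strategy (default): the variable's direction is summarized by the
#' pooled tau over all concatenated (value, attribution) pairs, and the
#' significance is a bootstrap sign test across the per-replicate taus:
#' p = 1 - max(frac tau > 0, frac tau < 0), the fraction of resampled refits
#' that fail to support the dominant direction, so at alpha = 0.1 the tau
#' sign must agree in more than 90% of replicates. Replicates in which the
#' variable was unused (degenerate tau: the ensemble never split on it)
#' count against sign stability. The tie-corrected normal p of the pooled
#' tau is reported for reference but is not the gate: concatenating B
#' dependent replicates inflates its effective sample size to the point
#' where any nonzero association is "significant".
#'
#' Consensus strategy: robust iff the median per-replicate tau p-value is
#' below `alpha` and the tau sign agrees in at least 80% of the assessable
#' replicates.
#'
#' Variables whose association is never assessable (constant values or
#' constant attributions) are never selected.
#'
#' @param report a `stability_report`.
#' @param alpha significance level, default 0.1.
#' @param strategy `"pooled"` or `"consensus"`.
#' @return Character vector of robust variable names.
#' @export
select_robust <- function(report, alpha = 0.1,
                          strategy = c("pooled", "consensus")) {
  strategy <- match.arg(strategy)
  vars <- report$variables
  pooled_tau <- vapply(report$pooled, `[[`, 0.0, "tau_b")
  if (strategy == "pooled") {
    vars[!is.na(pooled_tau) & report$sign_p < alpha]
  } else {
    med_p <- apply(report$p_replicates, 2, stats::median, na.rm = TRUE)
    vars[!is.na(med_p) & med_p < alpha &
           report$sign_consistency >= 0.8]
  }
}
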