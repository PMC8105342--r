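#' Serialize a stability report to JSON
#'
#' Stores everything needed to reproduce the robustness decision: B, seeds,
#' per-variable pooled tau/p, the per-replicate tau and p matrices, and the
#' sign-consistency fractions.
#'
#' @param report a `stability_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_json <- function(report, path) {
  payload <- list(
    B = report$B, n_eval = report$n_eval, seed = report$seed,
    estimator = report$estimator, output_space = report$output_space,
    variables = report$variables,
    replicate_seeds = report$replicate_seeds,
    pooled_tau = vapply(report$pooled, `[[`, 0.0, "tau_b"),
    pooled_p = vapply(report$pooled, `[[`, 0.0, "p_value"),
    pooled_n = vapply(report$pooled, `[[`, 0L, "n_pairs"),
    sign_consistency = unname(report$sign_consistency),
    sign_p = unname(report$sign_p),
    tau_replicates = report$tau_replicates,
    p_replicates = report$p_replicates)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_stability_json
#' @export
read_stability_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- p$variables
  pooled <- lapply(seq_along(vars), function(j)
    structure(list(tau_b = p$pooled_tau[j], p_value = p$pooled_p[j],
                   n_pairs = p$pooled_n[j]), class = "kendall_result"))
  names(pooled) <- vars
  tau <- matrix(unlist(p$tau_replicates), nrow = p$B, byrow = FALSE)
  pm <- matrix(unlist(p$p_replicates), nrow = p$B, byrow = FALSE)
  if (is.matrix(p$tau_replicates)) { tau <- p$tau_replicates; pm <- p$p_replicates }
  colnames(tau) <- vars; colnames(pm) <- vars
  structure(list(B = as.integer(p$B), variables = vars, pooled = pooled,
                 tau_replicates = tau, p_replicates = pm,
                 sign_consistency = stats::setNames(p$sign_consistency, vars),
                 sign_p = stats::setNames(p$sign_p, vars),
                 n_eval = as.integer(p$n_eval), seed = as.integer(p$seed),
                 replicate_seeds = p$replicate_seeds,
                 estimator = p$estimator, output_space = p$output_space),
            class = "stability_report")
}

#' Write the stability summary as CSV
#'
#' One row per variable: pooled tau, pooled p, sign-consistency, robust
#' decision at the given alpha.
#'
#' @inheritParams stability_summary
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_csv <- function(report, path, alpha = 0.1,
                                strategy = "pooled") {
  utils::write.csv(stability_summary(report, alpha, strategy), path,
                   row.names = FALSE)
  invisible(path)
}

#' Serialize an audit report to JSON
#'
#' @param audit an `audit_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audit_json <- function(audit, path) {
  payload <- list(
    table = audit$table, robust = audit$robust, flagged = audit$flagged,
    delta_p = lapply(audit$delta_p, function(d)
      list(variable = d$variable, v0 = d$v0, v1 = d$v1, mean = d$mean,
           min = d$min, max = d$max, delta = d$delta)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_audit_json
#' @export
read_audit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dp <- lapply(p$delta_p, function(d)
    structure(list(delta = d$delta, mean = d$mean, min = d$min, max = d$max,
                   variable = d$variable, v0 = d$v0, v1 = d$v1),
              class = "delta_p"))
  structure(list(table = as.data.frame(p$table), robust = p$robust,
                 flagged = as.character(p$flagged %||% character(0)),
                 delta_p = dp),
            class = "audit_report")
}

#' Serialize the three-stage framework metrics to JSON
#'
#' Emits, per stage (all / robust / intelligible variables), the six metrics
#' on the training, validation (cross-validation mean and SD over folds) and
#' test splits, plus the variable sets, the flagged variables, the split
#' seed, and a hash of the configuration.
#'
#' @param result a `framework_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_framework_json <- function(result, path) {
  stages <- lapply(result$stages, function(st) {
    m <- st$metrics
    out <- list(variables = st$variables,
                training = m$train[metric_names],
                test = m$test[metric_names])
    if (!is.null(m$validation)) {
      out$validation <- m$validation$mean[metric_names]
      out$validation_sd <- m$validation$sd[metric_names]
    }
    out
  })
  payload <- list(stages = stages,
                  variables = result$variables,
                  flagged = result$audit$flagged,
                  delta_p = lapply(result$audit$delta_p, function(d)
                    list(variable = d$variable, mean = d$mean, min = d$min,
                         max = d$max)),
                  seed = result$config$seed,
                  config_hash = config_hash(result$config),
                  decision_log = result$decision_log)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Hash a framework configuration
#'
#' Stable fingerprint of the full configuration (protocol constants, seed,
#' hyperparameters), stamped into every emitted artifact so runs can be
#' matched to their settings.
#'
#' @param config a [framework_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
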