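#' Declared clinical direction expectations
#'
#' One entry per variable: the direction domain experts expect the variable
#' to push predicted risk, plus a free-text provenance note citing the
#' knowledge source. Variables without an entry default to `"unknown"` and
#' are never flagged.
#'
#' @param name variable names.
#' @param expected_direction `"increases_risk"`, `"decreases_risk"` or
#'   `"unknown"` per variable.
#' @param note provenance notes (recycled).
#' @return A `direction_expectations` data frame.
#' @export
direction_expectations <- function(name, expected_direction,
                                   note = "") {
  assert_that(all(expected_direction %in%
                    c("increases_risk", "decreases_risk", "unknown")),
              "audit_error", "invalid expected_direction")
  out <- data.frame(name = as.character(name),
                    expected_direction = expected_direction,
                    note = rep_len(note, length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("direction_expectations", "data.frame")
  out
}

#' Read direction expectations from YAML
#'
#' Same dialect as the schema config: a mapping from variable name to keys
#' `expected_direction` and (optionally) `note`.
#'
#' @param path YAML path.
#' @return A [direction_expectations()].
#' @export
read_expectations <- function(path) {
  assert_that(file.exists(path), "io_error",
              "expectations file not found: %s", path)
  raw <- yaml::read_yaml(path)
  direction_expectations(
    name = names(raw),
    expected_direction = vapply(raw, function(v)
      v$expected_direction %||% "unknown", ""),
    note = vapply(raw, function(v) v$note %||% "", "")
  )
}

#' Expectations matching a synthetic ground truth
#'
#' Convenience for simulation studies: declares every causally harmful
#' variable (including the confounded one) as `increases_risk`, every
#' protective one as `decreases_risk`, and noise as `unknown`.
#'
#' @param truth the `ground_truth` from [generate_cohort()].
#' @return A [direction_expectations()].
#' @export
expectations_from_truth <- function(truth) {
  direction_expectations(
    name = truth$name,
    expected_direction = ifelse(truth$true_direction == "+", "increases_risk",
                         ifelse(truth$true_direction == "-", "decreases_risk",
                                "unknown")),
    note = ifelse(truth$true_direction == "null", "",
                  "planted causal direction"))
}

#' Flag robust variables whose behavior contradicts expectation
#'
#' Step 2 of the intelligible variable selection, machine part. The observed
#' direction of a robust variable is the sign of its pooled Kendall tau-b
#' from the stability report (positive tau means higher values push
#' predicted risk up). A variable is flagged `counterintuitive` iff a known
#' expectation contradicts that sign; variables with unknown expectation are
#' never flagged. The human confirmation happens in
#' [finalize_variables()] — flagging alone excludes nothing.
#'
#' @param stability a `stability_report` covering all robust variables.
#' @param expectations a [direction_expectations()].
#' @param robust character vector of robust variables (default: the pooled
#'   selection at alpha = 0.1).
#' @param alpha,strategy forwarded to [select_robust()] when `robust` is not
#'   supplied.
#' @return An `audit_report` with the per-variable flag table, the robust
#'   set, and an (initially empty) delta-p slot.
#' @export
flag_counterintuitive <- function(stability, expectations, robust = NULL,
                                  alpha = 0.1, strategy = "pooled") {
  if (is.null(robust)) robust <- select_robust(stability, alpha, strategy)
  missing <- setdiff(robust, stability$variables)
  assert_that(length(missing) == 0, "audit_error",
              "variable '%s' missing from stability report", missing[1])
  exp_dir <- stats::setNames(expectations$expected_direction,
                             expectations$name)
  tab <- do.call(rbind, lapply(robust, function(v) {
    tau <- stability$pooled[[v]]$tau_b
    observed <- if (is.na(tau) || tau == 0) "none" else
      if (tau > 0) "increases_risk" else "decreases_risk"
    expected <- unname(exp_dir[v]) %||% "unknown"
    if (is.na(expected)) expected <- "unknown"
    flag <- if (expected == "unknown" || observed == "none") {
      if (expected == "unknown") "unknown" else "consistent"
    } else if (expected == observed) "consistent" else "counterintuitive"
    data.frame(variable = v, pooled_tau = tau,
               observed_direction = observed,
               expected_direction = expected, flag = flag,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, robust = robust,
                 flagged = tab$variable[tab$flag == "counterintuitive"],
                 delta_p = list()),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %d robust variables; %d flagged counterintuitive\n",
              length(x$robust), length(x$flagged)))
  if (length(x$flagged)) {
    print(x$table[x$table$flag == "counterintuitive", , drop = FALSE])
  }
  invisible(x)
}

#' Counterfactual risk difference for one variable
#'
#' For every row, all other variables are held fixed while the audited
#' variable is set to `v0` and then `v1`; the per-patient difference in
#' predicted risk
#' \deqn{\delta p_i = \hat p(y_i = 1 \mid X_{i, -a}, X_a = v_0) -
#'       \hat p(y_i = 1 \mid X_{i, -a}, X_a = v_1)}
#' quantifies how much the model's score moves under the intervention. This
#' probes model behavior only; no causal claim is implied. For a binary
#' variable audited at (0, 1), a positive mean delta-p says the model treats
#' presence of the condition as protective.
#'
#' @param model a `risk_model`.
#' @param X complete feature matrix (typically the held-out test rows).
#' @param variable name of the audited variable.
#' @param v0,v1 the two intervention values (`v0 != v1`); defaults 0 and 1
#'   suit binary variables. For continuous variables pass explicit values
#'   (e.g. quartiles).
#' @return A `delta_p` object: the per-row `delta` vector, `mean`, `min`,
#'   `max`, the variable and intervention values.
#' @export
counterfactual_delta <- function(model, X, variable, v0 = 0, v1 = 1) {
  assert_that(variable %in% model$features, "audit_error",
              "variable '%s' not in model features", variable)
  assert_that(v0 != v1, "audit_error", "v0 and v1 must differ")
  X <- align_features(model, X)
  X0 <- X; X0[, variable] <- v0
  X1 <- X; X1[, variable] <- v1
  delta <- predict_risk(model, X0) - predict_risk(model, X1)
  structure(list(delta = delta, mean = mean(delta), min = min(delta),
                 max = max(delta), variable = variable, v0 = v0, v1 = v1),
            class = "delta_p")
}

#' @export
print.delta_p <- function(x, ...) {
  cat(sprintf("delta-p for '%s' (%g vs %g): mean %.4f, min %.4f, max %.4f over %d rows\n",
              x$variable, x$v0, x$v1, x$mean, x$min, x$max,
              length(x$delta)))
  invisible(x)
}

#' Confirm exclusions and produce the intelligible variable set
#'
#' Models the human-in-the-loop step: only variables the audit flagged as
#' counterintuitive can be confirmed for exclusion, and nothing is excluded
#' without confirmation. The intelligible set is the robust set minus the
#' confirmed exclusions.
#'
#' @param audit an `audit_report`.
#' @param confirm_exclusions variables to exclude; must be a subset of the
#'   flagged variables unless `override = TRUE`.
#' @param override allow excluding variables the audit did not flag.
#' @return Character vector of intelligible variables, with the decision
#'   trail in attribute `"decisions"`.
#' @export
finalize_variables <- function(audit, confirm_exclusions = character(),
                               override = FALSE) {
  extra <- setdiff(confirm_exclusions, audit$flagged)
  if (length(extra) > 0 && !override) {
    stop_classed("audit_error",
                 "variable '%s' was not flagged; pass override = TRUE to exclude it anyway",
                 extra[1])
  }
  unknown <- setdiff(confirm_exclusions, audit$robust)
  assert_that(length(unknown) == 0, "audit_error",
              "variable '%s' is not in the robust set", unknown[1])
  keep <- setdiff(audit$robust, confirm_exclusions)
  decisions <- data.frame(
    variable = audit$robust,
    action = ifelse(audit$robust %in% confirm_exclusions, "excluded",
                    "retained"),
    evidence = ifelse(audit$robust %in% audit$flagged,
                      "counterintuitive direction", "consistent/unknown"),
    stringsAsFactors = FALSE)
  attr(keep, "decisions") <- decisions
  keep
}
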