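#' Variable schema
#'
#' Declares, per variable, its measurement type, whether it is available at
#' hospital admission, whether it is a protected attribute (race/ethnicity-like
#' variables that are dropped outright to avoid encoding retrospective bias),
#' and optionally the clinically expected direction of effect used by the
#' knowledge audit.
#'
#' @param name character vector of variable names (unique).
#' @param vtype one of `"continuous"`, `"binary"`, `"ordinal"` per variable.
#' @param admission_time logical; is the variable available at admission?
#'   Variables that are not are dropped when a cohort is loaded.
#' @param protected logical; protected attributes are dropped when loaded.
#' @param expected_direction optional; one of `"increases_risk"`,
#'   `"decreases_risk"`, `"unknown"` per variable.
#' @return A `variable_schema` data frame.
#' @export
variable_schema <- function(name, vtype, admission_time = TRUE,
                            protected = FALSE,
                            expected_direction = "unknown") {
  assert_that(!anyDuplicated(name), "schema_error",
              "variable names must be unique")
  assert_that(all(vtype %in% c("continuous", "binary", "ordinal")),
              "schema_error",
              "vtype must be continuous, binary or ordinal")
  assert_that(all(expected_direction %in%
                    c("increases_risk", "decreases_risk", "unknown")),
              "schema_error", "invalid expected_direction")
  out <- data.frame(
    name = as.character(name),
    vtype = vtype,
    admission_time = rep_len(as.logical(admission_time), length(name)),
    protected = rep_len(as.logical(protected), length(name)),
    expected_direction = rep_len(expected_direction, length(name)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("variable_schema", "data.frame")
  out
}

#' Read a variable schema from a YAML config
#'
#' The file maps variable names to entries with keys `vtype`,
#' `admission_time`, `protected` and (optionally) `expected_direction`.
#'
#' @param path path to a YAML file.
#' @return A [variable_schema()].
#' @export
read_schema <- function(path) {
  assert_that(file.exists(path), "io_error", "schema file not found: %s", path)
  raw <- yaml::read_yaml(path)
  assert_that(length(raw) > 0, "schema_error", "empty schema file")
  variable_schema(
    name = names(raw),
    vtype = vapply(raw, function(v) v$vtype %||% "continuous", ""),
    admission_time = vapply(raw, function(v) isTRUE(v$admission_time %||% TRUE),
                            NA),
    protected = vapply(raw, function(v) isTRUE(v$protected %||% FALSE), NA),
    expected_direction = vapply(raw, function(v)
      v$expected_direction %||% "unknown", "")
  )
}

#' Write a variable schema to YAML
#'
#' @param schema a [variable_schema()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  entries <- lapply(seq_len(nrow(schema)), function(i) {
    list(vtype = schema$vtype[i],
         admission_time = schema$admission_time[i],
         protected = schema$protected[i],
         expected_direction = schema$expected_direction[i])
  })
  names(entries) <- schema$name
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Construct a cohort
#'
#' A cohort couples a patient-by-variable value matrix (missing values
#' allowed, coded `NA`), a binary outcome vector with 1 = unfavorable
#' outcome, the variable schema aligned with the matrix columns, and patient
#' identifiers. The convention throughout the package is that a "risk score"
#' is the predicted probability of the unfavorable class.
#'
#' @param X numeric matrix, one row per patient.
#' @param y outcome labels in \{0, 1\} (1 = unfavorable).
#' @param schema [variable_schema()] aligned with `colnames(X)`.
#' @param ids optional patient identifiers.
#' @return A `cohort` object.
#' @export
cohort <- function(X, y, schema, ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  assert_that(nrow(X) >= 1 && ncol(X) >= 1, "cohort_error",
              "cohort needs at least one row and one column")
  y <- as.integer(y)
  assert_that(length(y) == nrow(X), "cohort_error",
              "label length must equal row count")
  assert_that(all(y %in% c(0L, 1L)), "label_error",
              "labels must be 0/1 (1 = unfavorable)")
  assert_that(nrow(schema) == ncol(X), "schema_error",
              "schema length (%d) must equal column count (%d)",
              nrow(schema), ncol(X))
  assert_that(identical(schema$name, colnames(X)), "schema_error",
              "schema names must match matrix column names, in order")
  for (j in which(schema$vtype == "binary")) {
    v <- X[, j]
    assert_that(all(v[!is.na(v)] %in% c(0, 1)), "parse_error",
                "binary column '%s' has values outside {0, 1}",
                schema$name[j])
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  structure(list(X = X, y = y, schema = schema, ids = as.character(ids)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients x %d variables; prevalence %.3f; %d missing cells\n",
              nrow(x$X), ncol(x$X), mean(x$y), sum(is.na(x$X))))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$X)

subset_cohort <- function(ch, rows = NULL, vars = NULL) {
  X <- ch$X; y <- ch$y; ids <- ch$ids; schema <- ch$schema
  if (!is.null(rows)) { X <- X[rows, , drop = FALSE]; y <- y[rows]; ids <- ids[rows] }
  if (!is.null(vars)) {
    keep <- match(vars, colnames(X))
    assert_that(!anyNA(keep), "schema_error", "unknown variable requested")
    X <- X[, keep, drop = FALSE]
    schema <- schema[keep, , drop = FALSE]
    rownames(schema) <- NULL
  }
  structure(list(X = X, y = y, schema = schema, ids = ids), class = "cohort")
}

#' Dichotomize an extended Glasgow outcome score
#'
#' Maps the ordinal 1-8 functional outcome to the binary label used by the
#' prognostic model: scores of 4 and below (death, vegetative state, severe
#' disability) are the unfavorable class (1); 5-8 are favorable (0).
#'
#' @param gose integer vector with values in 1..8.
#' @return Integer vector of 0/1 labels.
#' @export
dichotomize_gose <- function(gose) {
  g <- as.numeric(gose)
  ok <- !is.na(g) & g == round(g) & g >= 1 & g <= 8
  assert_that(all(ok), "label_error",
              "outcome scores must be integers in 1..8 (offending value at row %s)",
              paste(which(!ok)[1]))
  as.integer(g <= 4)
}

#' Load a cohort from CSV
#'
#' Reads a header CSV (missing cells empty or `NA`), drops protected columns
#' and columns not available at admission time, validates binary columns, and
#' binds the outcome column. If the outcome column is declared `ordinal` in
#' the schema it is treated as a 1-8 functional outcome score and
#' dichotomized with [dichotomize_gose()]; otherwise it must already be 0/1.
#'
#' @param path CSV path.
#' @param schema [variable_schema()] describing the feature columns (the
#'   outcome column may, but need not, appear in it).
#' @param outcome_column name of the outcome column in the file.
#' @return A [cohort()].
#' @export
load_cohort <- function(path, schema, outcome_column) {
  assert_that(file.exists(path), "io_error", "cohort file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  assert_that(outcome_column %in% names(df), "schema_error",
              "outcome column '%s' not present in file", outcome_column)
  feat_schema <- schema[schema$name != outcome_column, , drop = FALSE]
  missing_cols <- setdiff(feat_schema$name, names(df))
  assert_that(length(missing_cols) == 0, "schema_error",
              "schema columns missing from file: %s",
              paste(missing_cols, collapse = ", "))

  keep <- feat_schema[!feat_schema$protected & feat_schema$admission_time, ,
                      drop = FALSE]
  rownames(keep) <- NULL
  X <- matrix(NA_real_, nrow(df), nrow(keep),
              dimnames = list(NULL, keep$name))
  for (j in seq_len(nrow(keep))) {
    col <- df[[keep$name[j]]]
    v <- suppressWarnings(as.numeric(as.character(col)))
    bad <- which(!is.na(as.character(col)) & is.na(v))
    assert_that(length(bad) == 0, "parse_error",
                "non-numeric value in column '%s', row %d",
                keep$name[j], if (length(bad)) bad[1] else 0L)
    X[, j] <- v
  }

  out_schema_row <- schema[schema$name == outcome_column, , drop = FALSE]
  yraw <- df[[outcome_column]]
  assert_that(!anyNA(yraw), "label_error", "outcome column has missing values")
  y <- if (nrow(out_schema_row) == 1 && out_schema_row$vtype == "ordinal") {
    dichotomize_gose(yraw)
  } else {
    assert_that(all(yraw %in% c(0, 1)), "label_error",
                "outcome values outside {0, 1}")
    as.integer(yraw)
  }
  cohort(X, y, keep)
}

#' Impute missing values with training-set column means
#'
#' Every missing cell in `apply_to` is replaced by the mean of the non-missing
#' values of that column in `train`; binary and ordinal columns are
#' mean-imputed exactly like continuous ones. Only training statistics are
#' used, so applying this to a held-out set leaks nothing.
#'
#' @param train cohort providing the column means.
#' @param apply_to cohort to fill (defaults to `train`).
#' @return `apply_to` with no missing feature values. The means used are
#'   attached as attribute `"column_means"`.
#' @export
impute_train_mean <- function(train, apply_to = train) {
  mu <- colMeans(train$X, na.rm = TRUE)
  bad <- names(mu)[is.nan(mu)]
  assert_that(length(bad) == 0, "imputation_error",
              "column '%s' has no observed training values", bad[1])
  assert_that(identical(colnames(train$X), colnames(apply_to$X)),
              "schema_error", "train and apply_to columns differ")
  X <- apply_to$X
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- unname(mu[j])
  }
  out <- apply_to
  out$X <- X
  attr(out, "column_means") <- mu
  out
}

#' Hold out a test fraction of a cohort
#'
#' Randomly sets aside `round(n * test_fraction)` rows (ties round half up)
#' as the final test set, by default stratified by outcome label so both
#' classes appear on both sides. The test rows are meant to stay untouched
#' until the prognostic model is finalized.
#'
#' @param cohort a [cohort()].
#' @param test_fraction proportion in (0, 1); default 0.25.
#' @param seed integer seed; the split is reproducible.
#' @param stratify stratify by label (default `TRUE`).
#' @return A `cohort_split` with `dev_indices`, `test_indices`, `seed`,
#'   `test_fraction`.
#' @export
holdout_split <- function(cohort, test_fraction = 0.25, seed = 1L,
                          stratify = TRUE) {
  n <- nrow(cohort$X)
  assert_that(test_fraction > 0 && test_fraction < 1, "split_error",
              "test_fraction must be in (0, 1)")
  n_test <- floor(n * test_fraction + 0.5)
  assert_that(n_test >= 1 && n_test < n, "split_error",
              "test fraction leaves an empty side")
  test_idx <- with_seed(seed, {
    if (stratify) {
      classes <- sort(unique(cohort$y))
      assert_that(length(classes) >= 2, "split_error",
                  "stratified split requires both classes")
      # largest-remainder apportionment of n_test across classes
      sizes <- vapply(classes, function(cl) sum(cohort$y == cl), 0L)
      quota <- n_test * sizes / n
      take <- floor(quota)
      rem <- order(quota - take, decreasing = TRUE)
      short <- n_test - sum(take)
      if (short > 0) take[rem[seq_len(short)]] <- take[rem[seq_len(short)]] + 1L
      assert_that(all(take >= 1) && all(sizes - take >= 1), "split_error",
                  "a class would be absent from one side of the split")
      sort(unlist(lapply(seq_along(classes), function(k) {
        pool <- which(cohort$y == classes[k])
        sample(pool, take[k])
      })))
    } else {
      sort(sample.int(n, n_test))
    }
  })
  structure(list(dev_indices = setdiff(seq_len(n), test_idx),
                 test_indices = test_idx,
                 seed = as.integer(seed),
                 test_fraction = test_fraction),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d development / %d test rows (fraction %.2f, seed %d)\n",
              length(x$dev_indices), length(x$test_indices),
              x$test_fraction, x$seed))
  invisible(x)
}
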