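test_that("outcome dichotomization splits the ordinal scale at 4", {
  expect_identical(dichotomize_gose(c(4, 5)), c(1L, 0L))
  expect_identical(dichotomize_gose(1), 1L)
  expect_identical(dichotomize_gose(8), 0L)
  expect_identical(dichotomize_gose(1:8), c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_error(dichotomize_gose(0), class = "label_error")
  expect_error(dichotomize_gose(9), class = "label_error")
  expect_error(dichotomize_gose(4.5), class = "label_error")
})

write_csv_fixture <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

test_that("loading drops protected and non-admission columns and keeps values", {
  df <- data.frame(age = c(30, 40, 50), race = c(1, 2, 1),
                   gcs = c(3, 7, 9), discharge_gcs = c(8, 9, 10),
                   outcome = c(1, 0, 1))
  sch <- variable_schema(
    c("age", "race", "gcs", "discharge_gcs"),
    vtype = "continuous",
    admission_time = c(TRUE, TRUE, TRUE, FALSE),
    protected = c(FALSE, TRUE, FALSE, FALSE))
  ch <- load_cohort(write_csv_fixture(df), sch, "outcome")
  expect_identical(colnames(ch$X), c("age", "gcs"))
  expect_identical(ch$X[, "age"], c(30, 40, 50))
  expect_identical(ch$y, c(1L, 0L, 1L))
})

test_that("a complete file loads identically and row order is preserved", {
  df <- data.frame(a = c(5, 1, 3), b = c(0, 1, 1), outcome = c(0, 1, 0))
  sch <- variable_schema(c("a", "b"), c("continuous", "binary"))
  ch <- load_cohort(write_csv_fixture(df), sch, "outcome")
  expect_identical(unname(ch$X), cbind(c(5, 1, 3), c(0, 1, 1)))
})

test_that("an ordinal outcome column is dichotomized on load", {
  df <- data.frame(a = 1:6, gose = c(1, 3, 4, 5, 7, 8))
  sch <- variable_schema(c("a", "gose"), c("continuous", "ordinal"))
  ch <- load_cohort(write_csv_fixture(df), sch, "gose")
  expect_identical(ch$y, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_identical(colnames(ch$X), "a")
})

test_that("load errors carry their cause", {
  df <- data.frame(a = c(1, 2), outcome = c(0, 1))
  sch <- variable_schema(c("a", "b"), "continuous")
  expect_error(load_cohort(write_csv_fixture(df), sch, "outcome"),
               class = "schema_error")
  df2 <- data.frame(a = c("1", "oops"), outcome = c(0, 1))
  expect_error(load_cohort(write_csv_fixture(df2),
                           variable_schema("a", "continuous"), "outcome"),
               "row 2", class = "parse_error")
  df3 <- data.frame(a = c(1, 2), outcome = c(0, 3))
  expect_error(load_cohort(write_csv_fixture(df3),
                           variable_schema("a", "continuous"), "outcome"),
               class = "label_error")
  df4 <- data.frame(a = c(1, 2), b = c(0, 2), outcome = c(0, 1))
  expect_error(load_cohort(write_csv_fixture(df4),
                           variable_schema(c("a", "b"),
                                           c("continuous", "binary")),
                           "outcome"),
               class = "parse_error")
})

test_that("schema YAML round-trips", {
  sch <- variable_schema(c("age", "race"), c("continuous", "binary"),
                         admission_time = c(TRUE, FALSE),
                         protected = c(FALSE, TRUE),
                         expected_direction = c("increases_risk", "unknown"))
  path <- tempfile(fileext = ".yaml")
  write_schema(sch, path)
  expect_equal(read_schema(path), sch)
})

make_cohort <- function(X, y) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  cohort(X, y, variable_schema(colnames(X), rep("continuous", ncol(X))))
}

test_that("imputation fills missing cells with training means only", {
  train <- make_cohort(cbind(c(1, 3, NA), c(0, 0, 1)), c(0, 1, 0))
  apply_to <- make_cohort(cbind(c(NA, 7), c(NA, 0)), c(1, 0))
  out <- impute_train_mean(train, apply_to)
  expect_equal(unname(out$X[1, 1]), 2.0)
  expect_equal(unname(out$X[2, 1]), 7)          # non-missing untouched
  expect_equal(unname(out$X[1, 2]), 1 / 3)
})

test_that("mean imputation applies to binary columns too", {
  train <- cohort(matrix(c(0, 0, 1, NA), 4, 1, dimnames = list(NULL, "b")),
                  c(0, 1, 0, 1), variable_schema("b", "binary"))
  out <- impute_train_mean(train)
  expect_equal(unname(out$X[4, 1]), 1 / 3)      # mean, not mode
})

test_that("imputation is idempotent and a no-op on complete data", {
  train <- toy_cohort(missing = 0.2)
  once <- impute_train_mean(train)
  twice <- impute_train_mean(once)
  expect_identical(once$X, twice$X)
  complete <- toy_cohort(missing = 0)
  expect_identical(impute_train_mean(train, complete)$X, complete$X)
})

test_that("imputed values do not depend on the target set (no leakage)", {
  train <- toy_cohort(seed = 1, missing = 0.2)
  target <- toy_cohort(seed = 2, missing = 0.3)
  miss <- is.na(target$X)
  perturbed <- target
  perturbed$X[!miss] <- perturbed$X[!miss] + 100  # change observed cells only
  a <- impute_train_mean(train, target)
  b <- impute_train_mean(train, perturbed)
  expect_identical(a$X[miss], b$X[miss])
  expect_identical(unname(a$X[miss][1]), mean(train$X[, col(train$X)[miss][1]],
                                      na.rm = TRUE))
})

test_that("imputation refuses an all-missing training column", {
  train <- make_cohort(cbind(c(NA, NA, NA), c(1, 2, 3)), c(0, 1, 0))
  expect_error(impute_train_mean(train), "f1", class = "imputation_error")
})

test_that("holdout split sizes round half up and are reproducible", {
  ch <- toy_cohort(n = 831, seed = 3)
  sp <- holdout_split(ch, 0.25, seed = 9)
  expect_length(sp$test_indices, 208)
  expect_length(sp$dev_indices, 623)
  sp2 <- holdout_split(ch, 0.25, seed = 9)
  expect_identical(sp$test_indices, sp2$test_indices)
  expect_false(identical(sp$test_indices,
                         holdout_split(ch, 0.25, seed = 10)$test_indices))
})

test_that("a stratified split keeps both classes on both sides", {
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("f1", "f2")))
  ch <- cohort(X, rep(c(0, 1), 4),
               variable_schema(c("f1", "f2"), "continuous"))
  sp <- holdout_split(ch, 0.25, seed = 4)
  expect_length(sp$test_indices, 2)
  expect_setequal(ch$y[sp$test_indices], c(0, 1))
  one_class <- cohort(X, rep(1L, 8) - c(1L, rep(0L, 7)),
                      variable_schema(c("f1", "f2"), "continuous"))
  expect_error(holdout_split(one_class, 0.25, seed = 1),
               class = "split_error")
})

test_that("dev and test always partition the cohort", {
  ch <- toy_cohort(n = 53)
  for (seed in 1:1000) {
    sp <- holdout_split(ch, 0.25, seed = seed)
    expect_identical(sort(c(sp$dev_indices, sp$test_indices)), 1:53)
  }
})
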