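test_that("a stumpless (constant) model attributes nothing", {
  set.seed(2)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0L, 1L), 10)
  # min_child_weight larger than n prevents any split: constant leaves
  m <- fit_gbm(X, y, default_hyperparameters(nrounds = 3,
                                             min_child_weight = 1e6),
               seed = 1)
  a <- explain(m, X, background = X, output_space = "log_odds")
  expect_true(all(a$phi == 0))
  expect_equal(a$base_value + rowSums(a$phi), a$fitted, tolerance = 1e-7)
})

test_that("a stump on one feature attributes only to that feature", {
  set.seed(3)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(X[, 1] > 0)
  m <- fit_gbm(X, y, default_hyperparameters(nrounds = 4, max_depth = 1,
                                             min_child_weight = 1),
               seed = 1)
  a <- explain(m, X[1:20, ], background = X, output_space = "log_odds")
  expect_true(all(a$phi[, 2:4] == 0))
  expect_true(any(a$phi[, 1] != 0))
})

test_that("the subset-enumeration oracle obeys the Shapley axioms", {
  set.seed(4)
  bg <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x <- rnorm(4)
  # linearity: an additive model attributes x_j - mean(background_j)
  phi <- exact_shapley(function(M) rowSums(M), x, bg)
  expect_equal(phi, x - colMeans(bg), tolerance = 1e-12,
               ignore_attr = TRUE)
  # dummy: a constant function attributes nothing
  expect_equal(exact_shapley(function(M) rep(2.5, nrow(M)), x, bg),
               rep(0, 4), tolerance = 1e-12)
  # symmetry: exchangeable features with equal values get equal credit
  bg2 <- cbind(bg[, 1], bg[, 1], bg[, 3:4])
  x2 <- c(1.3, 1.3, x[3:4])
  phi2 <- exact_shapley(function(M) (M[, 1] > 0) + (M[, 2] > 0) + M[, 3],
                        x2, bg2)
  expect_equal(phi2[1], phi2[2], tolerance = 1e-12)
  # efficiency: contributions sum to v(full) - v(empty)
  f <- function(M) plogis(M[, 1] * M[, 2] - M[, 3])
  phi3 <- exact_shapley(f, x, bg)
  expect_equal(sum(phi3), f(matrix(x, 1)) - mean(f(bg)), tolerance = 1e-12)
  expect_error(exact_shapley(f, rnorm(13), matrix(rnorm(26), 2, 13)),
               class = "size_error")
})

test_that("interventional attribution matches the exact oracle on small models", {
  for (seed in 1:6) {
    rm_ <- random_small_model(seed)
    bg <- rm_$X[seq_len(sample(4:16, 1)), , drop = FALSE]
    rows <- rm_$X[1:3, , drop = FALSE]
    a <- explain(rm_$model, rows, background = bg,
                 output_space = "log_odds", estimator = "interventional")
    pf <- function(M) predict_risk(rm_$model, M, output = "margin")
    for (i in 1:3) {
      expect_equal(a$phi[i, ], exact_shapley(pf, rows[i, ], bg),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("local accuracy holds in both output spaces and both estimators", {
  sim <- generate_cohort(sim_spec(n = 300, d_signal = 6, d_noise = 6,
                                  missing_rate = 0, seed = 6))
  ch <- sim$cohort
  m <- fit_gbm(ch$X, ch$y, default_hyperparameters(nrounds = 30), seed = 2)
  for (est in c("interventional", "tree_path")) {
    for (space in c("probability", "log_odds")) {
      a <- explain(m, ch$X[1:150, ], background = ch$X, output_space = space,
                   estimator = est, bg_cap = 128)
      target <- predict_risk(m, ch$X[1:150, ],
                             output = if (space == "probability")
                               "probability" else "margin")
      expect_lt(max(abs(a$base_value + rowSums(a$phi) - target)), 1e-6)
      expect_equal(a$fitted, target, tolerance = 1e-7)
    }
  }
})

test_that("attribution signs follow the risk convention", {
  # a feature that raises risk must accumulate positive phi at high values
  set.seed(9)
  X <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rbinom(300, 1, plogis(1.5 * X[, 1]))
  if (all(y == y[1])) y[1] <- 1L - y[1]
  m <- fit_gbm(X, y, default_hyperparameters(nrounds = 30), seed = 1)
  a <- explain(m, X, background = X)
  expect_gt(cor(X[, 1], a$phi[, "f1"], method = "kendall"), 0.5)
})

test_that("global importance ranks by mean absolute contribution", {
  a <- structure(list(
    phi = matrix(c(1, -1, -2, 2, 0, 0), 2, 3,
                 dimnames = list(NULL, c("v1", "v2", "v3"))),
    base_value = 0.4, output_space = "probability",
    fitted = c(0.4, 0.4), features = c("v1", "v2", "v3")),
    class = "attribution")
  imp <- global_importance(a)
  expect_identical(imp$variable, c("v2", "v1", "v3"))
  expect_equal(imp$importance, c(2, 1, 0))
  # homogeneity: scaling contributions scales importances, order unchanged
  a3 <- a; a3$phi <- a$phi * 3
  imp3 <- global_importance(a3)
  expect_identical(imp3$variable, imp$variable)
  expect_equal(imp3$importance, imp$importance * 3)
  # ties broken alphabetically
  a4 <- a; a4$phi <- matrix(c(1, -1, -1, 1, 0, 0), 2, 3,
                            dimnames = list(NULL, c("vb", "va", "vc")))
  a4$features <- c("vb", "va", "vc")
  expect_identical(global_importance(a4)$variable, c("va", "vb", "vc"))
})

test_that("attribution exports carry the data behind the plots", {
  tm <- toy_model()
  a <- explain(tm$model, tm$X[1:5, ], background = tm$X)
  path <- tempfile(fileext = ".csv")
  write_attribution_csv(a, path)
  lines <- readLines(path)
  expect_match(lines[1], "base_value")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(as.matrix(back), a$phi, ignore_attr = TRUE)
  fr <- force_records(a, tm$X[1:5, ], rows = 2)
  expect_equal(fr[[1]]$row, 2)
  expect_equal(fr[[1]]$base_value, a$base_value)
  expect_equal(sum(fr[[1]]$contributions$phi) + a$base_value,
               fr[[1]]$output, tolerance = 1e-7)
  # contributions are ordered by absolute size
  expect_false(is.unsorted(rev(abs(fr[[1]]$contributions$phi))))
})

test_that("explain guards empty backgrounds and missing values", {
  tm <- toy_model()
  expect_error(explain(tm$model, tm$X,
                       background = tm$X[0, , drop = FALSE]),
               class = "explanation_error")
  Xna <- tm$X; Xna[1, 1] <- NA
  expect_error(explain(tm$model, Xna, background = tm$X),
               class = "explanation_error")
})
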