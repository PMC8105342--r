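test_that("tau-b honors perfect concordance and discordance", {
  expect_equal(kendall_tau_b(1:5, c(2, 4, 6, 8, 10))$tau_b, 1.0)
  expect_equal(kendall_tau_b(1:5, 5:1)$tau_b, -1.0)
})

test_that("tau-b with ties matches explicit pair counting", {
  k <- kendall_tau_b(c(1, 1, 2, 3), c(1, 2, 2, 3))
  expect_equal(k$tau_b, kendall_oracle(c(1, 1, 2, 3), c(1, 2, 2, 3)),
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE)
    s <- round(rnorm(n), 1)
    expect_equal(kendall_tau_b(x, s)$tau_b, kendall_oracle(x, s),
                 tolerance = 1e-12)
  }
})

test_that("tau-b agrees with the reference implementation", {
  set.seed(11)
  x <- sample(1:8, 30, replace = TRUE)
  s <- round(rnorm(30), 1)
  ct <- suppressWarnings(stats::cor.test(x, s, method = "kendall",
                                         exact = FALSE))
  k <- kendall_tau_b(x, s)
  expect_equal(k$tau_b, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(k$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("the normal-approximation p tracks the exact permutation null", {
  set.seed(12)
  for (i in 1:5) {
    x <- sample(1:4, 8, replace = TRUE)
    s <- sample(1:5, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(s)) < 2) next
    p_norm <- kendall_tau_b(x, s)$p_value
    p_exact <- kendall_perm_p(x, s)
    expect_lt(abs(p_norm - p_exact), 0.08)
  }
})

test_that("tau-b is antisymmetric in either argument", {
  set.seed(13)
  x <- rnorm(25); s <- rnorm(25)
  expect_equal(kendall_tau_b(x, -s)$tau_b, -kendall_tau_b(x, s)$tau_b,
               tolerance = 1e-12)
  expect_equal(kendall_tau_b(-x, s)$tau_b, -kendall_tau_b(x, s)$tau_b,
               tolerance = 1e-12)
})

test_that("degenerate inputs raise a classed error", {
  expect_error(kendall_tau_b(rep(1, 5), 1:5),
               class = "degenerate_input_error")
  expect_error(kendall_tau_b(1:5, rep(2, 5)),
               class = "degenerate_input_error")
  expect_error(kendall_tau_b(1:2, 1:2), class = "degenerate_input_error")
  expect_error(kendall_tau_b(1:4, 1:5), class = "degenerate_input_error")
})

small_sim <- function(seed, n = 350) {
  generate_cohort(sim_spec(n = n, d_signal = 5, d_noise = 8,
                           confounder = list(enabled = FALSE),
                           missing_rate = 0.03, seed = seed))
}

test_that("the bootstrap screen is reproducible and structurally sound", {
  sim <- small_sim(1)
  hp <- default_hyperparameters(nrounds = 20)
  a <- bootstrap_stability(sim$cohort, B = 4, hyperparameters = hp, seed = 3)
  b <- bootstrap_stability(sim$cohort, B = 4, hyperparameters = hp, seed = 3)
  expect_identical(a$tau_replicates, b$tau_replicates)
  expect_identical(vapply(a$pooled, `[[`, 0.0, "tau_b"),
                   vapply(b$pooled, `[[`, 0.0, "tau_b"))
  expect_identical(a$variables, colnames(sim$cohort$X))
  expect_true(all(a$sign_p >= 0 & a$sign_p <= 1))
  expect_error(bootstrap_stability(sim$cohort, B = 1), class = "config_error")
})

test_that("noise associations are weaker than the strongest planted signal", {
  for (seed in 1:3) {
    sim <- small_sim(seed)
    st <- bootstrap_stability(sim$cohort, B = 10,
                              hyperparameters = default_hyperparameters(
                                nrounds = 25),
                              seed = seed)
    ptau <- abs(vapply(st$pooled, `[[`, 0.0, "tau_b"))
    sig <- sim$truth$name[sim$truth$true_direction != "null"]
    noi <- sim$truth$name[sim$truth$true_direction == "null"]
    expect_lt(max(ptau[noi], na.rm = TRUE), max(ptau[sig], na.rm = TRUE))
  }
})

test_that("a strong harmful signal keeps a positive tau in most replicates", {
  sim <- generate_cohort(sim_spec(seed = 2))
  split <- holdout_split(sim$cohort, 0.25, seed = 2)
  dev <- intelligible:::subset_cohort(sim$cohort,
                                      rows = split$dev_indices)
  st <- bootstrap_stability(dev, B = 20, seed = 5)
  # sig02 carries the strongest harmful continuous effect
  t <- st$tau_replicates[, "sig02"]
  expect_gte(mean(!is.na(t) & t > 0), 0.9)
})

test_that("pooled tau of the selected variables is stable in the replicate count", {
  sim <- generate_cohort(sim_spec(seed = 2))
  s1 <- bootstrap_stability(sim$cohort, B = 25, seed = 7)
  s2 <- bootstrap_stability(sim$cohort, B = 50, seed = 7)
  t1 <- vapply(s1$pooled, `[[`, 0.0, "tau_b")
  t2 <- vapply(s2$pooled, `[[`, 0.0, "tau_b")
  rob <- select_robust(s2, 0.1)
  expect_gt(length(rob), 10)
  expect_lt(max(abs(t1[rob] - t2[rob])), 0.05)
})

fake_report <- function(sign_p, pooled_tau = NULL, B = 50) {
  vars <- names(sign_p)
  if (is.null(pooled_tau)) pooled_tau <- rep(0.3, length(vars))
  pooled <- lapply(seq_along(vars), function(i)
    structure(list(tau_b = pooled_tau[i], p_value = 0.001, n_pairs = 100L),
              class = "kendall_result"))
  names(pooled) <- vars
  structure(list(B = B, variables = vars, pooled = pooled,
                 tau_replicates = matrix(0.1, B, length(vars),
                                         dimnames = list(NULL, vars)),
                 p_replicates = matrix(0.5, B, length(vars),
                                       dimnames = list(NULL, vars)),
                 sign_consistency = stats::setNames(1 - sign_p, vars),
                 sign_p = sign_p, n_eval = 100L, seed = 1L,
                 replicate_seeds = seq_len(B),
                 estimator = "tree_path", output_space = "log_odds"),
            class = "stability_report")
}

test_that("robust selection is a monotone threshold on the stability score", {
  rep_ <- fake_report(c(a = 0.005, b = 0.05, c = 0.09, d = 0.5, e = 0.2))
  expect_identical(select_robust(rep_, 0.1), c("a", "b", "c"))
  # clear non-significance is excluded
  expect_false("d" %in% select_robust(rep_, 0.1))
  # selection at a smaller alpha is nested in selection at a larger one
  for (al in c(0.01, 0.05, 0.1, 0.3)) {
    expect_true(all(select_robust(rep_, al) %in% select_robust(rep_, 0.4)))
  }
  # a variable that is never assessable is never selected
  rep2 <- fake_report(c(a = 0.0, b = 0.02))
  rep2$pooled$a$tau_b <- NA_real_
  expect_identical(select_robust(rep2, 0.1), "b")
})

test_that("an interaction-driven variable flips sign across refits while monotone signals hold", {
  # emulates the instability seen for some laboratory values: a variable
  # whose effect rides on an interaction has no stable marginal direction,
  # so its per-replicate tau sign flips while monotone signals never flip
  inter_cons <- main_cons <- c()
  for (seed in 40:42) {
    set.seed(seed)
    n <- 300
    X <- cbind(main1 = rnorm(n), main2 = rnorm(n),
               inter = rnorm(n), partner = rnorm(n), n1 = rnorm(n),
               n2 = rnorm(n))
    y <- rbinom(n, 1, plogis(-0.1 + 1.2 * X[, "main1"] -
                               1.0 * X[, "main2"] +
                               0.8 * X[, "inter"] * X[, "partner"]))
    ch <- cohort(X, y, variable_schema(colnames(X), "continuous"))
    st <- bootstrap_stability(ch, B = 25,
                              hyperparameters = default_hyperparameters(
                                nrounds = 40, min_child_weight = 4),
                              seed = 8)
    inter_cons <- c(inter_cons, st$sign_consistency[["inter"]])
    main_cons <- c(main_cons, st$sign_consistency[["main1"]],
                   st$sign_consistency[["main2"]])
  }
  expect_lt(min(inter_cons), 0.8)          # flips occur under resampling
  expect_true(all(main_cons >= 0.9))       # monotone signals never flip
  expect_lt(mean(inter_cons), mean(main_cons))
})

test_that("stability reports summarize and serialize losslessly", {
  sim <- small_sim(4)
  st <- bootstrap_stability(sim$cohort, B = 5,
                            hyperparameters = default_hyperparameters(
                              nrounds = 10),
                            seed = 2)
  df <- stability_summary(st, alpha = 0.1)
  expect_identical(df$variable, st$variables)
  expect_identical(df$robust, df$variable %in% select_robust(st, 0.1))
  path <- tempfile(fileext = ".json")
  write_stability_json(st, path)
  back <- read_stability_json(path)
  expect_equal(vapply(back$pooled, `[[`, 0.0, "tau_b"),
               vapply(st$pooled, `[[`, 0.0, "tau_b"))
  expect_equal(back$tau_replicates, st$tau_replicates)
  expect_equal(back$sign_p, st$sign_p)
  expect_identical(back$B, st$B)
  csv <- tempfile(fileext = ".csv")
  write_stability_csv(st, csv)
  expect_equal(utils::read.csv(csv)$pooled_tau, df$pooled_tau)
})
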