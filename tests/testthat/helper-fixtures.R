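# Shared fixtures and independent oracles, all built in code.

# --- small cohorts ---------------------------------------------------------

toy_cohort <- function(n = 40, d = 3, seed = 11, missing = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", seq_len(d))))
  y <- rbinom(n, 1, plogis(X[, 1]))
  if (all(y == y[1])) y[1] <- 1L - y[1]
  if (missing > 0) X[matrix(runif(n * d) < missing, n, d)] <- NA
  cohort(X, y, variable_schema(colnames(X), rep("continuous", d)))
}

# linearly separable two-feature set
separable_data <- function(n = 20) {
  X <- cbind(f1 = c(seq(-2, -0.5, length.out = n / 2),
                    seq(0.5, 2, length.out = n / 2)),
             f2 = rep(c(-1, 1), n / 2))
  y <- rep(c(0L, 1L), each = n / 2)
  list(X = X, y = y)
}

# small fitted booster for attribution tests
toy_model <- function(n = 80, d = 4, seed = 5, nrounds = 10, max_depth = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", seq_len(d))))
  y <- rbinom(n, 1, plogis(X[, 1] - 0.8 * X[, 2]))
  if (all(y == y[1])) y[1] <- 1L - y[1]
  list(model = fit_gbm(X, y, default_hyperparameters(
    nrounds = nrounds, max_depth = max_depth, min_child_weight = 2),
    seed = seed), X = X, y = y)
}

# --- independent oracles ---------------------------------------------------

# O(n^2) Kendall tau-b by explicit pair counting with tie corrections
kendall_oracle <- function(x, s) {
  n <- length(x)
  C <- D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    prod <- sign(x[i] - x[j]) * sign(s[i] - s[j])
    if (prod > 0) C <- C + 1 else if (prod < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2))
  n2 <- sum(choose(table(s), 2))
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# exact permutation p-value for tau at tiny n: all n! orderings of s
kendall_perm_p <- function(x, s) {
  n <- length(x)
  stopifnot(n <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  # statistic: C - D (tau-b shares the same permutation ordering since the
  # tie corrections are permutation-invariant)
  cmd <- function(xx, ss) {
    tot <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tot <- tot + sign(xx[i] - xx[j]) * sign(ss[i] - ss[j])
    }
    tot
  }
  obs <- abs(cmd(x, s))
  all_p <- perms(seq_len(n))
  hits <- vapply(all_p, function(p) abs(cmd(x, s[p])) >= obs - 1e-9, NA)
  mean(hits)
}

# explicit confusion-matrix metrics + pairwise AUC
metrics_oracle <- function(y, scores, threshold = 0.5) {
  pos <- which(y == 1); neg <- which(y == 0)
  gt <- half <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) gt <- gt + 1
    else if (scores[i] == scores[j]) half <- half + 1
  }
  auc <- (gt + 0.5 * half) / (length(pos) * length(neg))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- tp / (tp + fn)
  list(auc = auc, accuracy = (tp + tn) / length(y),
       f1 = if (!is.na(prec) && prec + sens > 0)
         2 * prec * sens / (prec + sens) else NA_real_,
       sensitivity = sens, specificity = tn / (tn + fp), precision = prec)
}

# random small booster for oracle-equivalence checks
random_small_model <- function(seed, d = NULL, n = 60) {
  set.seed(seed)
  if (is.null(d)) d <- sample(3:8, 1)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("v", seq_len(d))))
  y <- rbinom(n, 1, plogis(X %*% rnorm(d, sd = 0.8)))
  if (all(y == y[1])) y[1] <- 1L - y[1]
  hp <- default_hyperparameters(nrounds = sample(3:8, 1),
                                max_depth = sample(2:4, 1),
                                min_child_weight = 2)
  list(model = fit_gbm(X, y, hp, seed = seed), X = X, d = d)
}
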