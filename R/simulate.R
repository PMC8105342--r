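#' Specification of a synthetic cohort
#'
#' Describes a seeded synthetic tabular cohort with a recoverable ground
#' truth: planted signal features with monotone effects on a logistic
#' outcome, pure-noise features, optionally one confounded binary feature
#' whose causal effect is harmful while its marginal association is
#' protective (it is generated to co-occur with low values of a strongly
#' protective covariate, the way substance use co-occurs with youth in
#' trauma cohorts), and missing-completely-at-random cells.
#'
#' Signal features are standard-normal continuous variables and Bernoulli
#' binary variables (roughly 70/30 by count); binary coefficients are scaled
#' up so that effective effect sizes are comparable across types. The default
#' cohort is sized like a mid-size clinical trial: n = 831, 20 signal and 40
#' noise variables, outcome prevalence near 0.42.
#'
#' @param n sample count (>= 20).
#' @param d_signal number of true-effect features.
#' @param d_noise number of null features.
#' @param beta optional per-signal log-odds coefficients (recycled); by
#'   default a tapered profile from strong to moderate effects with
#'   alternating signs, the first (strongly protective, continuous) feature
#'   anchoring the confounder link.
#' @param intercept log-odds intercept; the default targets prevalence
#'   around 0.42.
#' @param confounder list with `enabled`, `causal_beta` (harmful, > 0),
#'   `link_rho` (latent Gaussian correlation with the measured protective
#'   anchor feature, |rho| < 1), `prevalence`, and the unmeasured protective
#'   pathway: `latent_rho` (correlation of the confounder's latent score
#'   with an unmeasured factor U) and `latent_beta` (U's log-odds effect on
#'   the outcome, protective when negative). The unmeasured pathway is what
#'   makes the confounded variable genuinely informative to the fitted
#'   model — a proxy for protection the model cannot otherwise see.
#' @param missing_rate MCAR missingness proportion in [0, 0.5).
#' @param seed integer seed; generation is fully reproducible.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(n = 831L,
                     d_signal = 20L,
                     d_noise = 40L,
                     beta = NULL,
                     intercept = -0.88,
                     confounder = list(enabled = TRUE, causal_beta = 0.2,
                                       link_rho = 0.85, prevalence = 0.35,
                                       latent_rho = 0.4,
                                       latent_beta = -1.2),
                     missing_rate = 0.05,
                     seed = 1L) {
  assert_that(n >= 20, "spec_error", "n must be at least 20")
  assert_that(d_signal >= 1 && d_noise >= 0, "spec_error",
              "need at least one signal feature")
  assert_that(missing_rate >= 0 && missing_rate < 0.5, "spec_error",
              "missing_rate must be in [0, 0.5)")
  confounder <- utils::modifyList(
    list(enabled = TRUE, causal_beta = 0.2, link_rho = 0.85,
         prevalence = 0.35, latent_rho = 0.4, latent_beta = -1.2),
    confounder)
  if (isTRUE(confounder$enabled)) {
    assert_that(confounder$causal_beta > 0, "spec_error",
                "causal_beta must be > 0 (harmful) when confounder enabled")
    assert_that(abs(confounder$link_rho) < 1, "spec_error",
                "|link_rho| must be < 1")
    assert_that(confounder$link_rho^2 + confounder$latent_rho^2 < 1,
                "spec_error", "link_rho^2 + latent_rho^2 must be < 1")
  }
  n_cont <- max(1L, ceiling(0.7 * d_signal))
  n_bin <- d_signal - n_cont
  if (is.null(beta)) {
    # the first continuous signal is the strongly protective anchor the
    # confounder links to; the rest taper with alternating signs
    beta_cont <- c(-1.6, if (n_cont > 1)
      seq(0.8, 0.35, length.out = n_cont - 1) * rep_len(c(1, -1), n_cont - 1))
    beta_bin <- if (n_bin > 0) {
      seq(1.2, 0.7, length.out = n_bin) * rep_len(c(1, -1), n_bin)
    } else numeric(0)
    beta <- c(beta_cont, beta_bin)
  } else {
    beta <- rep_len(beta, d_signal)
    # keep the confounder anchor protective
    if (isTRUE(confounder$enabled)) beta[1] <- -abs(beta[1])
  }
  structure(list(n = as.integer(n), d_signal = as.integer(d_signal),
                 d_noise = as.integer(d_noise), n_cont = n_cont,
                 n_bin = n_bin, beta = beta, intercept = intercept,
                 confounder = confounder, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> n=%d, %d signal (%d continuous, %d binary), %d noise, confounder %s, missing %.2f, seed %d\n",
    x$n, x$d_signal, x$n_cont, x$n_bin, x$d_noise,
    if (isTRUE(x$confounder$enabled)) "on" else "off",
    x$missing_rate, x$seed))
  invisible(x)
}

sim_feature_names <- function(spec) {
  nm <- c(sprintf("sig%02d", seq_len(spec$n_cont)),
          if (spec$n_bin > 0) sprintf("sigb%02d", seq_len(spec$n_bin)))
  if (isTRUE(spec$confounder$enabled)) nm <- c(nm, "conf01")
  n_noise_bin <- floor(0.25 * spec$d_noise)
  n_noise_cont <- spec$d_noise - n_noise_bin
  c(nm,
    if (n_noise_cont > 0) sprintf("noise%02d", seq_len(n_noise_cont)),
    if (n_noise_bin > 0) sprintf("noiseb%02d", seq_len(n_noise_bin)))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws features per the specification, generates the binary outcome from
#' the logistic model over the true (complete) feature values, then masks
#' cells completely at random. When the confounder is enabled, the binary
#' variable `conf01` is generated by thresholding a Gaussian latent score
#' correlated (at `link_rho`) with the first, strongly protective,
#' continuous signal; its causal log-odds effect `causal_beta` is harmful,
#' but its marginal association with the outcome is protective.
#'
#' @param spec a [sim_spec()].
#' @return A list with elements `cohort` (a [cohort()]); `truth`, a
#'   `ground_truth` data frame with one row per generated column
#'   (`true_direction` in \{`+`, `-`, `null`\}, the causal coefficient, and
#'   a `confounded` flag); and `latent`, the unmeasured protective factor U
#'   (or `NULL`), kept so simulation studies can verify that adjusting for
#'   the full planted confounding pathway recovers the causal sign.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  nm <- sim_feature_names(spec)
  n <- spec$n
  with_seed(spec$seed, {
    Xc <- matrix(rnorm(n * spec$n_cont), n, spec$n_cont)
    Xb <- if (spec$n_bin > 0) {
      matrix(rbinom(n * spec$n_bin, 1, 0.35), n, spec$n_bin)
    } else NULL
    lp <- spec$intercept + Xc %*% spec$beta[seq_len(spec$n_cont)]
    if (spec$n_bin > 0) {
      lp <- lp + Xb %*% spec$beta[spec$n_cont + seq_len(spec$n_bin)]
    }
    A <- NULL
    if (isTRUE(spec$confounder$enabled)) {
      rho <- spec$confounder$link_rho
      rho_u <- spec$confounder$latent_rho
      # latent score correlated with the protective anchor Z = Xc[,1]
      # (beta_Z < 0, so high Z is the low-risk side) and optionally with an
      # unmeasured protective factor U: A = 1 co-occurs with protection, the
      # way substance use co-occurs with youth and low-severity mechanisms,
      # so its marginal association is protective despite the harmful
      # causal effect
      U <- rnorm(n)
      latent <- rho * Xc[, 1] + rho_u * U +
        sqrt(1 - rho^2 - rho_u^2) * rnorm(n)
      A <- as.integer(latent > qnorm(1 - spec$confounder$prevalence))
      lp <- lp + spec$confounder$causal_beta * A +
        spec$confounder$latent_beta * U
    }
    y <- rbinom(n, 1, sigmoid(lp))

    n_noise_bin <- floor(0.25 * spec$d_noise)
    n_noise_cont <- spec$d_noise - n_noise_bin
    Nc <- if (n_noise_cont > 0) matrix(rnorm(n * n_noise_cont), n, n_noise_cont) else NULL
    Nb <- if (n_noise_bin > 0) matrix(rbinom(n * n_noise_bin, 1, 0.35), n, n_noise_bin) else NULL

    X <- cbind(Xc, Xb, A, Nc, Nb)
    colnames(X) <- nm

    vtype <- c(rep("continuous", spec$n_cont), rep("binary", spec$n_bin),
               if (!is.null(A)) "binary",
               rep("continuous", n_noise_cont), rep("binary", n_noise_bin))
    schema <- variable_schema(nm, vtype)
    ch <- cohort(X, y, schema)
    if (spec$missing_rate > 0) {
      ch <- plant_missingness(ch, spec$missing_rate,
                              seed = spec$seed + 1L)
    }

    causal <- c(spec$beta, if (!is.null(A)) spec$confounder$causal_beta,
                rep(0, n_noise_cont + n_noise_bin))
    truth <- data.frame(
      name = nm,
      true_direction = ifelse(causal > 0, "+", ifelse(causal < 0, "-", "null")),
      causal_beta = causal,
      confounded = nm == "conf01",
      stringsAsFactors = FALSE
    )
    class(truth) <- c("ground_truth", "data.frame")
    list(cohort = ch, truth = truth,
         latent = if (!is.null(A)) U else NULL)
  })
}

#' Mask feature cells completely at random
#'
#' Each feature cell is set missing independently with probability `rate`;
#' outcome labels are never masked.
#'
#' @param cohort a [cohort()].
#' @param rate missingness probability in [0, 0.5).
#' @param seed integer seed.
#' @return The cohort with `NA` cells planted.
#' @export
plant_missingness <- function(cohort, rate, seed = 1L) {
  assert_that(rate >= 0 && rate < 0.5, "spec_error",
              "rate must be in [0, 0.5)")
  if (rate == 0) return(cohort)
  mask <- with_seed(seed, matrix(stats::runif(length(cohort$X)) < rate,
                                 nrow(cohort$X), ncol(cohort$X)))
  cohort$X[mask] <- NA_real_
  cohort
}

#' Write the simulator outputs to disk
#'
#' Writes the cohort as CSV (features plus an `outcome` column), the schema
#' as YAML, and the ground truth as JSON.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(dir, "cohort.csv")
  schema_path <- file.path(dir, "schema.yaml")
  truth_path <- file.path(dir, "ground_truth.json")
  df <- as.data.frame(sim$cohort$X)
  df$outcome <- sim$cohort$y
  utils::write.csv(df, cohort_path, row.names = FALSE, na = "")
  write_schema(sim$cohort$schema, schema_path)
  jsonlite::write_json(sim$truth, truth_path, dataframe = "columns",
                       digits = NA)
  invisible(c(cohort = cohort_path, schema = schema_path, truth = truth_path))
}
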