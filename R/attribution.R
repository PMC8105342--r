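#' Parse a fitted booster into flat leaf tables
#'
#' Walks the JSON dump of each tree, collapsing path constraints per leaf to
#' one half-open interval `[lo, hi)` per distinct feature. These tables feed
#' the compiled interventional Shapley backend and the double-precision
#' margin evaluator.
#'
#' @param model a `risk_model`.
#' @return List of per-tree tables (internal layout).
#' @keywords internal
parse_booster_trees <- function(model) {
  dump <- xgboost::xgb.dump(model$booster, dump_format = "json")
  trees <- jsonlite::fromJSON(dump, simplifyVector = FALSE)
  feat_idx <- stats::setNames(seq_along(model$features) - 1L,
                              model$features)
  lapply(trees, function(tree) {
    leaf_value <- numeric(0)
    cons_leaf <- list()
    walk <- function(node, lo, hi) {
      if (!is.null(node$leaf)) {
        leaf_value[length(leaf_value) + 1L] <<- node$leaf
        active <- which(is.finite(lo) | is.finite(hi))
        cons_leaf[[length(cons_leaf) + 1L]] <<- list(
          feat = active - 1L, lo = lo[active], hi = hi[active])
        return(invisible())
      }
      f <- node$split
      j <- if (f %in% names(feat_idx)) feat_idx[[f]] + 1L else {
        # dump may use f<idx> when names were unavailable
        as.integer(sub("^f", "", f)) + 1L
      }
      t <- node$split_condition
      yes_id <- node$yes; no_id <- node$no
      for (ch in node$children) {
        if (ch$nodeid == yes_id) {        # x < t
          hi2 <- hi; hi2[j] <- min(hi2[j], t)
          walk(ch, lo, hi2)
        } else if (ch$nodeid == no_id) {  # x >= t
          lo2 <- lo; lo2[j] <- max(lo2[j], t)
          walk(ch, lo2, hi)
        }
      }
      invisible()
    }
    d <- length(model$features)
    walk(tree, rep(-Inf, d), rep(Inf, d))
    nlf <- length(leaf_value)
    counts <- vapply(cons_leaf, function(cl) length(cl$feat), 0L)
    list(leaf_value = leaf_value,
         cons_start = as.integer(c(0L, cumsum(counts))),
         cons_feat = as.integer(unlist(lapply(cons_leaf, `[[`, "feat"))),
         cons_lo = as.numeric(unlist(lapply(cons_leaf, `[[`, "lo"))),
         cons_hi = as.numeric(unlist(lapply(cons_leaf, `[[`, "hi"))))
  })
}

#' Per-patient attribution of predicted risk
#'
#' Distributes each prediction, relative to a base value, across the input
#' variables as Shapley values. Two estimators are available:
#'
#' * `"interventional"` (default): exact Shapley values of the interventional
#'   value function v(S) = mean over background rows of the model applied to
#'   the explicand on S and the background row elsewhere, computed in the
#'   ensemble's native log-odds space by exact per-leaf enumeration (no
#'   sampling error). The base value is the mean background margin.
#' * `"tree_path"`: the fast path-dependent tree recursion shipped with the
#'   booster (cover-weighted), log-odds space; the base value is its bias
#'   term. Preferred inside heavy resampling loops.
#'
#' Attributions are reported either in log-odds, where tree ensembles are
#' natively additive, or in probability space, obtained by rescaling each
#' row's log-odds attributions by (p(x) - p_base) / (m(x) - m_base) so local
#' accuracy — base value plus row sum equals the prediction — holds exactly
#' in the declared space. Positive values raise the predicted risk.
#'
#' @param model a `risk_model`.
#' @param X complete matrix of rows to explain.
#' @param background complete background matrix (interventional estimator);
#'   defaults to `X`. Capped at `bg_cap` rows by a seeded subsample.
#' @param output_space `"probability"` (default) or `"log_odds"`.
#' @param estimator `"interventional"` or `"tree_path"`.
#' @param bg_cap background row cap, default 512.
#' @param seed seed for the background subsample.
#' @return An `attribution` object: `phi` (n x d), `base_value`,
#'   `output_space`, `estimator`, `fitted` (model output per row in the
#'   declared space), `features`.
#' @export
explain <- function(model, X, background = NULL,
                    output_space = c("probability", "log_odds"),
                    estimator = c("interventional", "tree_path"),
                    bg_cap = 512L, seed = 1L) {
  output_space <- match.arg(output_space)
  estimator <- match.arg(estimator)
  X <- align_features(model, X)
  assert_that(!anyNA(X), "explanation_error",
              "matrix to explain contains missing values")

  margin <- predict_risk(model, X, output = "margin")
  prob <- sigmoid(margin)

  if (estimator == "interventional") {
    if (is.null(background)) background <- X
    background <- align_features(model, background)
    assert_that(nrow(background) >= 1, "explanation_error",
                "background is empty")
    assert_that(!anyNA(background), "explanation_error",
                "background contains missing values")
    if (nrow(background) > bg_cap) {
      keep <- with_seed(seed, sample.int(nrow(background), bg_cap))
      background <- background[keep, , drop = FALSE]
    }
    trees <- parse_booster_trees(model)
    phi <- interventional_shap_cpp(trees, X, background)
    # double-precision margins from the parsed trees; the ensemble's
    # constant offset (float32 in the booster) is recovered by averaging
    margin_dd <- tree_margin_cpp(trees, X)
    offset <- mean(margin - margin_dd)
    margin <- margin_dd + offset
    prob <- sigmoid(margin)
    base_margin <- mean(tree_margin_cpp(trees, background)) + offset
  } else {
    d <- xgboost::xgb.DMatrix(X, nthread = 1)
    ctr <- predict(model$booster, d, predcontrib = TRUE)
    bias_col <- ncol(ctr)  # intercept column is last
    base_margin <- ctr[1, bias_col]
    phi <- ctr[, -bias_col, drop = FALSE]
  }
  colnames(phi) <- model$features

  if (output_space == "probability") {
    base_value <- sigmoid(base_margin)
    denom <- margin - base_margin
    scale <- ifelse(abs(denom) > 1e-9,
                    (prob - base_value) / denom,
                    base_value * (1 - base_value))
    phi <- phi * scale
    fitted <- prob
  } else {
    base_value <- base_margin
    fitted <- margin
  }
  structure(list(phi = phi, base_value = base_value,
                 output_space = output_space, estimator = estimator,
                 fitted = fitted, features = model$features),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution> %d rows x %d variables (%s, %s); base value %.4f\n",
              nrow(x$phi), ncol(x$phi), x$estimator, x$output_space,
              x$base_value))
  invisible(x)
}

#' Exact Shapley values by subset enumeration
#'
#' Brute-force oracle for small feature sets: enumerates all 2^d coalitions
#' of the interventional value function v(S) = mean over background rows of
#' `predict_fn` applied to `x` on S and the background row elsewhere, and
#' accumulates the weighted marginal contributions
#' |S|! (d - |S| - 1)! / d!. Satisfies efficiency, symmetry and the dummy
#' axiom by construction. Intended to verify [explain()]; limited to
#' d <= 12.
#'
#' @param predict_fn function mapping a numeric matrix to a score vector.
#' @param x single row (numeric vector or 1-row matrix).
#' @param background background matrix.
#' @param feature_set integer columns to attribute over (default all).
#' @return Numeric vector of Shapley values, one per feature of `x`
#'   (features outside `feature_set` get 0).
#' @export
exact_shapley <- function(predict_fn, x, background,
                          feature_set = seq_len(ncol(background))) {
  x <- as.numeric(x)
  background <- as.matrix(background)
  d <- length(feature_set)
  assert_that(d >= 1 && d <= 12, "size_error",
              "subset enumeration limited to 1..12 features")
  nb <- nrow(background)
  assert_that(nb >= 1, "explanation_error", "background is empty")

  # v(S) for every coalition: build all composites, one predict call
  n_sub <- 2L^d
  comp <- background[rep(seq_len(nb), n_sub), , drop = FALSE]
  for (s in 0:(n_sub - 1L)) {
    members <- feature_set[bitwAnd(s, bitwShiftL(1L, 0:(d - 1L))) != 0L]
    if (length(members) > 0) {
      rows <- s * nb + seq_len(nb)
      comp[rows, members] <- matrix(x[members], nb, length(members),
                                    byrow = TRUE)
    }
  }
  if (!is.null(colnames(background))) colnames(comp) <- colnames(background)
  v <- colMeans(matrix(predict_fn(comp), nrow = nb))
  w <- factorial(0:(d - 1L)) * factorial(d - 1L - 0:(d - 1L)) / factorial(d)
  phi <- numeric(length(x))
  for (k in seq_len(d)) {
    bit <- bitwShiftL(1L, k - 1L)
    contrib <- 0
    for (s in 0:(n_sub - 1L)) {
      if (bitwAnd(s, bit) != 0L) next
      size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(d - 1L))) != 0L)
      contrib <- contrib + w[size + 1L] * (v[s + bit + 1L] - v[s + 1L])
    }
    phi[feature_set[k]] <- contrib
  }
  phi
}

#' Global variable importance
#'
#' Ranks variables by the mean absolute attribution over the explained
#' population; ties are broken alphabetically.
#'
#' @param attr an `attribution`.
#' @return An `importance_ranking` data frame with columns `variable` and
#'   `importance`, sorted descending.
#' @export
global_importance <- function(attr) {
  imp <- colMeans(abs(attr$phi))
  ord <- order(-imp, names(imp))
  out <- data.frame(variable = names(imp)[ord],
                    importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Export an attribution matrix to CSV
#'
#' Rows are patients, columns are variables; the base value and output space
#' are recorded in comment header lines.
#'
#' @param attr an `attribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attribution_csv <- function(attr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# base_value: %.17g", attr$base_value), con)
  writeLines(sprintf("# output_space: %s", attr$output_space), con)
  utils::write.csv(as.data.frame(attr$phi), con, row.names = FALSE)
  invisible(path)
}

#' Per-patient force records
#'
#' The data behind a per-patient force plot: for each explained row, the
#' base value, the model output, and one record per variable (name, input
#' value, attribution), ordered by absolute contribution.
#'
#' @param attr an `attribution`.
#' @param X the matrix that was explained (for the variable values).
#' @param rows which rows to export (default all).
#' @return List of per-patient records (serializable to JSON).
#' @export
force_records <- function(attr, X, rows = seq_len(nrow(attr$phi))) {
  X <- as.matrix(X)[, attr$features, drop = FALSE]
  lapply(rows, function(i) {
    ord <- order(-abs(attr$phi[i, ]))
    list(row = i,
         base_value = attr$base_value,
         output = attr$fitted[i],
         output_space = attr$output_space,
         contributions = data.frame(
           variable = attr$features[ord],
           value = unname(X[i, ord]),
           phi = unname(attr$phi[i, ord]),
           stringsAsFactors = FALSE))
  })
}
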