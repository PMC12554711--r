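#' Prognostic-model configuration
#'
#' Settings for the support-vector-regression model that predicts a
#' subject's scale-score change from their selected EEG feature changes,
#' its leave-one-out evaluation, and the permutation significance test.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param C Regularization weight (> 0).
#' @param epsilon Insensitive-tube width (>= 0).
#' @param gamma RBF kernel width; `NULL` (default) uses
#'   1 / (d x mean feature variance) computed on each training fold.
#' @param n_permutations Size of the permutation null (default 5000).
#' @param seed Integer RNG seed for the permutations.
#' @param standardize Standardize predictors with training-fold statistics
#'   (default `TRUE`).
#' @return A `model_config` list.
#' @export
model_config <- function(kernel = c("rbf", "linear"), C = 1, epsilon = 0.1,
                         gamma = NULL, n_permutations = 5000, seed = 1L,
                         standardize = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, epsilon >= 0, n_permutations >= 100)
  structure(
    list(kernel = kernel, C = C, epsilon = epsilon, gamma = gamma,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed),
         standardize = standardize),
    class = "model_config"
  )
}

# fit on (X, y), predict newx; standardization and constant-column dropping
# use training data only so the held-out subject never leaks into scaling
svr_fit_predict <- function(X, y, newx, cfg) {
  n <- nrow(X)
  mu <- colMeans(X)
  vars <- (colMeans(X^2) - mu^2) * n / (n - 1)
  vars[vars < 0] <- 0
  keep <- vars > 0
  if (!any(keep)) return(mean(y))          # no informative predictor
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant column(s) in training fold")
    X <- X[, keep, drop = FALSE]
    newx <- newx[, keep, drop = FALSE]
    mu <- mu[keep]; vars <- vars[keep]
  }
  if (cfg$standardize) {
    sd_tr <- sqrt(vars)
    X <- sweep(sweep(X, 2, mu), 2, sd_tr, "/")
    newx <- sweep(sweep(newx, 2, mu), 2, sd_tr, "/")
    mean_var <- 1
  } else {
    mean_var <- mean(vars)
  }
  gamma <- cfg$gamma %||% (1 / (ncol(X) * mean_var))
  fit <- e1071::svm(
    X, y, type = "eps-regression",
    kernel = if (cfg$kernel == "rbf") "radial" else "linear",
    cost = cfg$C, epsilon = cfg$epsilon, gamma = gamma, scale = FALSE
  )
  unname(stats::predict(fit, newx))
}

#' Leave-one-out SVR predictions
#'
#' For each subject, fits the SVR on the remaining subjects (standardizing
#' with their statistics only) and predicts the held-out subject's outcome.
#'
#' @param X Numeric matrix, subjects x predictors (no missing values).
#' @param y Outcome vector (scale-score change).
#' @param cfg A [model_config()].
#' @param select_fn Optional function `(X_train, y_train) -> column
#'   indices`, re-applied inside every fold (nested selection).
#' @return Numeric vector of leave-one-out predictions, one per subject.
#' @export
loo_predict <- function(X, y, cfg = model_config(), select_fn = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("leave-one-out SVR needs at least 4 subjects")
  if (anyNA(X)) stop("X contains missing values")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  vapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (!is.null(select_fn)) {
      cols <- select_fn(Xtr, ytr)
      if (length(cols) == 0) return(mean(ytr))
      Xtr <- Xtr[, cols, drop = FALSE]
      Xte <- X[i, cols, drop = FALSE]
    } else {
      Xte <- X[i, , drop = FALSE]
    }
    svr_fit_predict(Xtr, ytr, Xte, cfg)
  }, numeric(1))
}

#' Correlation between predicted and true outcomes
#'
#' @param pred,y Equal-length numeric vectors with positive SD.
#' @return Pearson r.
#' @export
prediction_correlation <- function(pred, y) {
  if (length(pred) != length(y)) stop("length mismatch")
  if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero-variance vector")
  }
  stats::cor(pred, y)
}

#' Permutation significance test of the leave-one-out SVR
#'
#' The observed statistic is the Pearson correlation between leave-one-out
#' predictions and the true outcomes. The null distribution is built by
#' randomly reassigning the predictor rows to subjects (outcomes fixed) and
#' recomputing the full leave-one-out correlation each time. The p-value is
#' one-sided toward positive correlation with the add-one finite-sample
#' correction: p = (#\{null r >= observed r\} + 1) / (n_permutations + 1).
#'
#' @inheritParams loo_predict
#' @return An `eeg_permutation` object: `observed_r`, `loo_predictions`,
#'   `null_rs`, `p`, `n_permutations`, `seed`, `y`, `config`.
#' @export
permutation_test <- function(X, y, cfg = model_config(), select_fn = NULL) {
  X <- as.matrix(X)
  if (stats::sd(y) == 0) stop("outcome has zero variance")
  pred <- loo_predict(X, y, cfg, select_fn)
  if (stats::sd(pred) == 0) {
    warning("degenerate predictions (zero variance); observed r set to 0")
    observed <- 0
  } else {
    observed <- prediction_correlation(pred, y)
  }
  null_rs <- with_local_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(b) {
      Xp <- X[sample(nrow(X)), , drop = FALSE]
      pb <- loo_predict(Xp, y, cfg, select_fn)
      if (stats::sd(pb) == 0) 0 else stats::cor(pb, y)
    }, numeric(1))
  })
  p <- (sum(null_rs >= observed) + 1) / (cfg$n_permutations + 1)
  structure(
    list(observed_r = observed, loo_predictions = pred, null_rs = null_rs,
         p = p, n_permutations = cfg$n_permutations, seed = cfg$seed,
         y = y, config = cfg, n_selected = ncol(X), selected = colnames(X)),
    class = "eeg_permutation"
  )
}

#' @export
print.eeg_permutation <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<eeg_permutation> empty model: no significant indicators selected\n")
    return(invisible(x))
  }
  cat(sprintf("<eeg_permutation> observed r = %.4f, permutation p = %.4f (%d permutations, seed %d)\n",
              x$observed_r, x$p, x$n_permutations, x$seed))
  invisible(x)
}

#' Run the full prognostic analysis for one scale
#'
#' Builds per-subject feature changes, correlates every indicator-channel
#' with the scale change, selects the significant ones, and runs the
#' permutation-validated leave-one-out SVR on the selected changes.
#'
#' In `"full"` selection mode (the default) the indicators are selected
#' once on the full sample before cross-validation — simple but optimistic,
#' since the held-out subject contributes to the selection. `"nested"` mode
#' repeats the selection inside every leave-one-out fold (and every
#' permutation), which is leakage-free.
#'
#' @param features Long feature tibble from [extract_features()].
#' @param scores Scale tibble.
#' @param scale `"psqi"` or `"isi"`.
#' @param alpha Selection significance level (default 0.05).
#' @param cfg A [model_config()].
#' @param selection `"full"` or `"nested"`.
#' @param correction Multiple-testing correction for the selection
#'   (default `"none"`).
#' @return An `eeg_permutation`; when no indicator is selected, an empty
#'   result with `empty = TRUE` and `NA` statistics.
#' @export
run_prognosis <- function(features, scores, scale = c("psqi", "isi"),
                          alpha = 0.05, cfg = model_config(),
                          selection = c("full", "nested"),
                          correction = "none") {
  scale <- match.arg(scale)
  selection <- match.arg(selection)
  diffs <- feature_differences(features)
  sdiffs <- scale_differences(scores)
  common <- intersect(unique(diffs$subject_id), sdiffs$subject_id)
  if (length(common) < 4) stop("need at least 4 subjects with complete data")

  wide <- diffs |>
    dplyr::mutate(indicator = paste(.data$feature, .data$band, .data$channel,
                                    sep = ".")) |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "indicator",
                       values_from = "delta")
  wide <- wide[match(common, wide$subject_id), , drop = FALSE]
  X_all <- as.matrix(wide[, -1, drop = FALSE])
  y <- sdiffs[[paste0("delta_", scale)]][match(common, sdiffs$subject_id)]
  complete_cols <- colSums(!is.finite(X_all)) == 0
  X_all <- X_all[, complete_cols, drop = FALSE]

  if (selection == "nested") {
    select_fn <- function(Xtr, ytr) which(grid_cor_p(Xtr, ytr) < alpha)
    res <- permutation_test(X_all, y, cfg, select_fn = select_fn)
    res$scale <- scale
    res$selection <- "nested"
    return(res)
  }

  cors <- correlate_with_outcome(diffs, sdiffs, scale)
  sel <- select_significant(cors, alpha = alpha, correction = correction)
  if (nrow(sel) == 0) {
    return(structure(
      list(observed_r = NA_real_, loo_predictions = rep(NA_real_, length(y)),
           null_rs = numeric(0), p = NA_real_,
           n_permutations = cfg$n_permutations, seed = cfg$seed, y = y,
           config = cfg, n_selected = 0L, selected = character(0),
           scale = scale, selection = "full", empty = TRUE),
      class = "eeg_permutation"
    ))
  }
  keys <- paste(sel$feature, sel$band, sel$channel, sep = ".")
  X <- X_all[, intersect(keys, colnames(X_all)), drop = FALSE]
  res <- permutation_test(X, y, cfg)
  res$scale <- scale
  res$selection <- "full"
  res
}

# vectorized two-tailed Pearson p-values of each column of X against y
grid_cor_p <- function(X, y) {
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok)) r[ok] <- suppressWarnings(as.vector(stats::cor(X[, ok, drop = FALSE], y)))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!ok] <- 1
  p
}
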