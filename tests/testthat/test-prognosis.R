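test_that("LOO SVR recovers a near-identity mapping", {
  set.seed(1)
  y <- rnorm(15)
  X <- matrix(y, ncol = 1)
  cfg <- model_config(kernel = "linear", C = 100, epsilon = 0.001,
                      n_permutations = 200, seed = 3)
  pred <- loo_predict(X, y, cfg)
  expect_length(pred, 15)
  expect_gt(prediction_correlation(pred, y), 0.95)
})

test_that("prognosis preconditions and degenerate outcomes are caught", {
  set.seed(2)
  X <- matrix(rnorm(9), ncol = 3)
  expect_error(loo_predict(X, rnorm(3)), "at least 4")
  X6 <- matrix(rnorm(18), ncol = 3)
  expect_error(loo_predict(X6, rnorm(5)), "length")
  X6[2, 1] <- NA
  expect_error(loo_predict(X6, rnorm(6)), "missing")
  expect_error(permutation_test(matrix(rnorm(24), ncol = 2), rep(1, 12)),
               "zero variance")
  expect_error(prediction_correlation(rep(1, 5), rnorm(5)), "zero-variance")
  expect_equal(prediction_correlation(1:5, 1:5), 1)
  expect_equal(prediction_correlation(1:5, -(1:5)), -1)
})

test_that("training-fold statistics never leak from the held-out subject", {
  set.seed(5)
  n <- 8
  y <- rnorm(n)
  X <- cbind(y + rnorm(n, sd = 0.1), c(99, rep(1, n - 1)))
  colnames(X) <- c("signal", "flat")
  cfg <- model_config(seed = 1, n_permutations = 100)
  # fold 1's training rows see a constant second column: it must be dropped,
  # so subject 1's prediction ignores their own extreme value in that column
  expect_warning(pred <- loo_predict(X, y, cfg), "constant column")
  pred_ref <- suppressWarnings(
    loo_predict(X[, "signal", drop = FALSE], y, cfg)
  )
  expect_equal(pred[1], pred_ref[1])
})

test_that("permutation results are deterministic and correctly assembled", {
  set.seed(8)
  y <- rnorm(10)
  X <- matrix(y + rnorm(10, sd = 0.4), ncol = 1)
  cfg <- model_config(n_permutations = 150, seed = 42)
  res1 <- permutation_test(X, y, cfg)
  res2 <- permutation_test(X, y, cfg)
  expect_identical(res1$null_rs, res2$null_rs)
  expect_identical(res1$p, res2$p)
  expect_length(res1$null_rs, 150)
  # p implements the add-one one-sided formula on its own null distribution
  expect_equal(res1$p, (sum(res1$null_rs >= res1$observed_r) + 1) / 151)
  expect_gt(res1$p, 0)
  expect_lte(res1$p, 1)
  g <- glance(res1)
  expect_equal(g$n_permutations, 150)
  expect_equal(g$observed_r, res1$observed_r)
  td <- tidy(res1)
  expect_equal(nrow(td), 10)
  expect_equal(td$observed, y)
})

test_that("the default configuration requests a 5000-draw null", {
  expect_equal(model_config()$n_permutations, 5000)
  expect_error(model_config(n_permutations = 10), "n_permutations")
  expect_error(model_config(C = -1), "C > 0")
})

test_that("a strong planted linear signal is detected", {
  set.seed(13)
  n <- 15
  X <- matrix(rnorm(n * 3), ncol = 3)
  y <- X %*% c(1, -0.5, 0.25) + rnorm(n, sd = 0.2)
  cfg <- model_config(n_permutations = 1000, seed = 7)
  res <- permutation_test(X, as.vector(y), cfg)
  expect_lte(res$p, 0.01)
})

test_that("end-to-end prognosis selects indicators and returns both scales", {
  cohort <- generate_cohort(test_synth_config(
    n_subjects = 10, seed = 303, effect_size = 0.04, effect_scale = "psqi"
  ))
  ft <- suppressMessages(extract_features(cohort))
  cfg <- model_config(n_permutations = 100, seed = 5)
  res_psqi <- run_prognosis(ft, cohort$scores, "psqi", cfg = cfg)
  res_isi <- run_prognosis(ft, cohort$scores, "isi", cfg = cfg)
  expect_s3_class(res_psqi, "eeg_permutation")
  expect_false(identical(res_psqi$p, res_isi$p))
  expect_gt(res_psqi$n_selected, 0)
  expect_length(res_psqi$loo_predictions, 10)

  # impossible selection threshold -> explicit empty-model result
  empty <- run_prognosis(ft, cohort$scores, "psqi", alpha = 1e-12, cfg = cfg)
  expect_true(empty$empty)
  expect_true(is.na(empty$p))
  expect_equal(empty$n_selected, 0L)
})

test_that("nested selection keeps the null rejection rate near alpha", {
  # predictors independent of the outcome; selection re-done in every fold
  set.seed(99)
  cfg <- model_config(n_permutations = 100, seed = 17)
  rejections <- vapply(1:25, function(k) {
    set.seed(7000 + k)
    X <- matrix(rnorm(12 * 40), ncol = 40,
                dimnames = list(NULL, paste0("c", 1:40)))
    y <- rnorm(12)
    sel_fn <- function(Xtr, ytr) which(eegprognosr:::grid_cor_p(Xtr, ytr) < 0.05)
    res <- permutation_test(X, y, cfg, select_fn = sel_fn)
    res$p <= 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.1)
})
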