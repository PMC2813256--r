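#' K-fold cross-validation with F-test acceptance
#'
#' Randomly partitions the experiment-replicate rows into `k` approximately
#' equal folds; each fold is predicted by a PLS model fitted on the other
#' `k - 1` folds under the same component-selection rule as the full model.
#' Acceptance requires all three of:
#'
#' * test-vs-train similarity: `F = mean test MSE / mean train MSE` has
#'   cumulative F probability below 0.95 (degrees of freedom: total test
#'   residual count minus 1; total train residual count minus the predictor
#'   count minus 1);
#' * better-than-random: the mean cross-validated SSE of `n_random`
#'   output-shuffled models must exceed the actual mean test SSE in a
#'   one-sided F-test at p < 0.05;
#' * variance gate: the full-data PLS model captures at least 50% of the
#'   output variance.
#'
#' @param X,y Normalized inputs and output.
#' @param k Fold count (default 10).
#' @param n_random Number of output-shuffled null models (default 100).
#' @param seed Integer seed; fold assignment and shuffles are reproducible.
#' @param max_components Passed to [fit_pls1()].
#' @param output Optional output name.
#' @param variance_threshold Minimum training R^2 (default 0.5).
#' @return Object of class `phos_validation` with per-fold SSEs, the F
#'   statistics and probabilities, the acceptance flag and its three
#'   components.
#' @export
kfold_validate <- function(X, y, k = 10, n_random = 100, seed = 1,
                           max_components = ncol(X), output = NULL,
                           variance_threshold = 0.5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  check_number(k, "k", lower = 2, integerish = TRUE)
  if (n < 2 * k) abort("Need at least 2k rows for k-fold validation.")
  check_number(n_random, "n_random", lower = 1, integerish = TRUE)
  local_seed_if(seed)

  folds <- sample(rep_len(seq_len(k), n))

  cv_sse <- function(yv) {
    test_sse <- numeric(k)
    train_sse <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      eng <- pls1_engine(X[tr, , drop = FALSE], yv[tr], max_components)
      m <- min(select_components(eng$varfrac), eng$rank)
      b <- pls1_coef(eng, m)
      train_sse[f] <- sum((yv[tr] - X[tr, , drop = FALSE] %*% b)^2)
      test_sse[f] <- sum((yv[!tr] - X[!tr, , drop = FALSE] %*% b)^2)
    }
    list(test = test_sse, train = train_sse)
  }

  actual <- cv_sse(y)
  n_test_total <- n
  n_train_total <- n * (k - 1L)
  mse_test <- sum(actual$test) / n_test_total
  mse_train <- sum(actual$train) / n_train_total

  df1 <- n_test_total - 1L
  df2 <- n_train_total - p - 1L
  f_tt <- if (mse_train < 1e-12 && mse_test < 1e-12) 1 else mse_test / mse_train
  p_tt <- pf(f_tt, df1, df2)

  random_test_mse <- vapply(seq_len(n_random), function(i) {
    sum(cv_sse(sample(y))$test) / n_test_total
  }, numeric(1))
  mse_rand <- mean(random_test_mse)
  f_rand <- if (mse_test < 1e-12) Inf else mse_rand / mse_test
  p_rand <- 1 - pf(f_rand, n_random * n_test_total - 1L, df1)

  full <- fit_pls1(X, y, max_components = max_components, output = output)
  pass_var <- full$r_squared >= variance_threshold
  pass_tt <- p_tt < 0.95
  pass_rand <- p_rand < 0.05

  structure(
    list(
      output = output %||% "y",
      k = k, folds = folds, seed = seed,
      test_sse = actual$test, train_sse = actual$train,
      f_statistic = f_tt, f_probability = p_tt,
      random_test_mse = random_test_mse,
      p_random = p_rand,
      r_squared = full$r_squared,
      n_components = full$n_components,
      pass_train_test = pass_tt,
      pass_random = pass_rand,
      pass_variance = pass_var,
      accepted = pass_tt && pass_rand && pass_var,
      n = n
    ),
    class = "phos_validation"
  )
}

#' @export
print.phos_validation <- function(x, ...) {
  cat(sprintf(
    paste0("<phos_validation> output %s: k = %d, F = %.3f (P = %.3f), ",
           "p_random = %.3g, R^2 = %.3f -> %s\n"),
    x$output, x$k, x$f_statistic, x$f_probability, x$p_random, x$r_squared,
    if (x$accepted) "accepted" else "rejected"
  ))
  invisible(x)
}
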