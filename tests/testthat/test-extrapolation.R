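test_that("pseudo-rate is the Euler-consistent rate", {
  B <- diag(3)
  expect_equal(pseudo_rate(B, 2), matrix(0, 3, 3))
  withr::local_seed(70)
  B <- matrix(rnorm(9, sd = 0.3), 3, 3) + diag(3) * 0.5
  K <- pseudo_rate(B, 2)
  x <- rnorm(3)
  # one Euler step of size delta_t reproduces B %*% x exactly
  expect_equal(x + 2 * drop(K %*% x), drop(B %*% x))
  expect_error(pseudo_rate(B, 0), "delta_t")
  expect_error(pseudo_rate(matrix(1, 2, 3), 1), "square")
})

test_that("diagonal systems match the scalar closed form", {
  lam <- c(0.9, 0.6, 0.3)
  K <- pseudo_rate(diag(lam), 2)
  x0 <- matrix(c(1, -2, 0.5), 1)
  xt <- integrate_linear(x0, K, t_span = 7, step = 0.01)
  expect_equal(as.vector(xt), as.vector(x0) * exp((lam - 1) / 2 * 7),
               tolerance = 1e-6)
})

test_that("RK4 matches the matrix-exponential solution", {
  skip_if_not_installed("pracma")
  withr::local_seed(71)
  K <- matrix(rnorm(16, sd = 0.15), 4, 4) - diag(4) * 0.2
  X0 <- matrix(rnorm(12), 3, 4)
  got <- integrate_linear(X0, K, t_span = 7, step = 0.01)
  want <- X0 %*% t(pracma::expm(K * 7))
  expect_lt(max(abs(got - want)), 1e-6)

  # affine variant against the closed form x(t) = e^{Kt}x0 + K^{-1}(e^{Kt}-I)k0
  k0 <- rnorm(4, sd = 0.1)
  got_a <- integrate_linear(X0, K, k0, t_span = 5, step = 0.01)
  EK <- pracma::expm(K * 5)
  part <- solve(K, (EK - diag(4)) %*% k0)
  want_a <- X0 %*% t(EK) + matrix(part, 3, 4, byrow = TRUE)
  expect_lt(max(abs(got_a - want_a)), 1e-6)
})

test_that("halving the integration step barely changes the result", {
  withr::local_seed(72)
  K <- matrix(rnorm(9, sd = 0.2), 3, 3) - diag(3) * 0.3
  X0 <- matrix(rnorm(6), 2, 3)
  a <- integrate_linear(X0, K, t_span = 7, step = 0.02)
  b <- integrate_linear(X0, K, t_span = 7, step = 0.01)
  expect_lt(max(abs(a - b)), 1e-8)
})

# screen whose log2 trajectories follow a continuous linear ODE exactly,
# so extrapolation with the matrix-log rate convention must reproduce the
# horizon state to numerical accuracy
continuous_screen <- function(K, n_cases = 40, times = c(0, 1, 3, 10),
                              seed = 73) {
  skip_if_not_installed("pracma")
  withr::local_seed(seed)
  n <- nrow(K)
  prot <- sprintf("PP%02d", seq_len(n))
  dimnames(K) <- list(prot, prot)
  X1 <- matrix(rnorm(n_cases * n), n_cases, n) # state at t = 1 (impulse)
  states <- list(`0` = X1 * 0, `1` = X1)
  for (t in setdiff(times, c(0, 1))) {
    states[[as.character(t)]] <- X1 %*% t(pracma::expm(K * (t - 1)))
  }
  rows <- purrr::map_dfr(seq_len(n_cases), function(i) {
    purrr::map_dfr(times, function(t) {
      tibble::tibble(
        experiment_id = sprintf("E%04d", i),
        ligands = "LPS", replicate = 1L, time_min = t, protein = prot,
        fold_change = 2^states[[as.character(t)]][i, ]
      )
    })
  })
  as_screen(rows)
}

test_that("a continuous linear system is extrapolated to numerical accuracy", {
  skip_if_not_installed("pracma")
  withr::local_seed(74)
  n <- 4
  K <- matrix(rnorm(n * n, sd = 0.1), n, n) - diag(n) * 0.25
  scr <- continuous_screen(K)
  pairs <- zscore_normalize(build_lag_pairs(scr, 1, 3))
  prot <- colnames(pairs$X)
  # minimal models on the full predictor set: exact least-squares recovery
  models <- lapply(prot, function(o) {
    fit_minimal(pairs$X, pairs$Y[, o], prot, output = o)
  })
  names(models) <- prot
  analysis <- list(minimal_models = models, pairs = pairs,
                   t_in = 1, t_out = 3)
  ex <- extrapolate(analysis, scr, t_start = 3, t_end = 10, step = 0.01,
                    method = "logm")
  err <- abs(ex$predictions$predicted - ex$predictions$observed)
  expect_lt(max(err), 1e-5)
})

test_that("zero-span extrapolation returns the initial state", {
  skip_if_not_installed("pracma")
  withr::local_seed(75)
  K <- matrix(rnorm(9, sd = 0.1), 3, 3) - diag(3) * 0.2
  scr <- continuous_screen(K, n_cases = 10, times = c(0, 1, 3))
  pairs <- zscore_normalize(build_lag_pairs(scr, 1, 3))
  prot <- colnames(pairs$X)
  models <- setNames(lapply(prot, function(o) {
    fit_minimal(pairs$X, pairs$Y[, o], prot, output = o)
  }), prot)
  analysis <- list(minimal_models = models, pairs = pairs, t_in = 1, t_out = 3)
  expect_warning(
    ex <- extrapolate(analysis, scr, t_start = 3, t_end = 3),
    NA
  )
  at3 <- scr[scr$time_min == 3, ]
  joined <- dplyr::inner_join(
    ex$predictions, dplyr::mutate(at3, obs3 = log2(fold_change)),
    by = c("experiment_id", "replicate", "protein")
  )
  expect_lt(max(abs(joined$predicted - joined$obs3)), 1e-10)
})

test_that("band fractions from extrapolation are ordered and bounded", {
  truth <- generate_ground_truth(5, 0.2, seed = 76)
  scr <- simulate_screen(truth, n_conditions = 40, seed = 77)
  ana <- analyze_screen(scr, n_random = 20, n_shuffles = 150, seed = 78)
  skip_if(length(ana$minimal_models) == 0)
  ex <- extrapolate(ana, scr, t_start = 3, t_end = 10)
  expect_true(all(ex$bands$frac_2sig >= ex$bands$frac_1sig))
  expect_true(all(ex$bands$frac_1sig >= 0 & ex$bands$frac_2sig <= 1))
  gl <- glance(ex)
  expect_equal(gl$frac_2sig, mean(ex$bands$frac_2sig))
})
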