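test_that("confidence thresholds match the normal quantile", {
  expect_equal(round(threshold_for_confidence(0.99), 2), 2.58)
  expect_equal(round(threshold_for_confidence(0.95), 2), 1.96)
  expect_gt(threshold_for_confidence(0.999), threshold_for_confidence(0.99))
  expect_error(threshold_for_confidence(1), "level")
  expect_error(threshold_for_confidence(0), "level")
})

test_that("permutation null is centred, reproducible, and guarded", {
  withr::local_seed(20)
  X <- scale(matrix(rnorm(80 * 4), 80, 4))[, , drop = FALSE]
  colnames(X) <- paste0("x", 1:4)
  y <- scale(drop(X %*% c(1, 0.5, 0, 0)) + rnorm(80, sd = 0.4))[, 1]

  n1 <- permutation_null(X, y, n_shuffles = 400, seed = 21)
  n2 <- permutation_null(X, y, n_shuffles = 400, seed = 21)
  expect_identical(n1$sigma, n2$sigma)
  expect_true(all(n1$sigma > 0))
  # null mean within 3 sigma / sqrt(n_shuffles) of zero, per input
  tol <- 3 * n1$sigma / sqrt(400)
  expect_true(all(abs(colMeans(n1$coefficients)) < tol))

  expect_warning(permutation_null(X, y, n_shuffles = 50, seed = 1),
                 "unstable")
  expect_error(permutation_null(X, rep(1, 80), n_shuffles = 100, seed = 1),
               "Constant")
})

test_that("masks follow the ratio threshold, two-sided with near band", {
  B <- matrix(c(3.0, -2.4, 0, 1.0), 2, 2,
              dimnames = list(c("o1", "o2"), c("i1", "i2")))
  sigma <- matrix(1, 2, 2, dimnames = dimnames(B))
  et <- significant_edges(B, sigma, level = 0.99)
  expect_true(et$significant["o1", "i1"])        # r = 3.0 > 2.58
  expect_false(et$significant["o2", "i1"])       # |r| = 2.4
  expect_true(et$near_significant["o2", "i1"])   # 2.4 >= 0.9 * 2.58 = 2.322
  expect_false(et$near_significant["o2", "i2"])
  expect_true(all(et$significant[et$near_significant == FALSE] == FALSE))
  # near-significant mask contains the significant mask
  expect_true(all(!(et$significant & !et$near_significant)))

  z <- significant_edges(B * 0, sigma, level = 0.99)
  expect_equal(sum(z$significant), 0)
  expect_equal(sum(z$near_significant), 0)

  sigma[1, 1] <- 0
  expect_error(significant_edges(B, sigma), "zero")
  expect_error(significant_edges(B, matrix(1, 3, 3)), "congruent")
})

test_that("noise-free sparse system: exact signed support recovery", {
  # with the all-component (least-squares-equivalent) fit, zero-noise
  # coefficients are exactly the rows of B_true: zeros stay zero (ratio 0)
  # and every cross edge is recovered with its sign
  truth <- generate_ground_truth(8, cross_density = 0.2, seed = 30,
                                 noise_sd = 0)
  scr <- simulate_screen(truth, n_conditions = 80, replicates = 1,
                         timepoints = c(0, 1, 3), seed = 31)
  pairs <- zscore_normalize(build_lag_pairs(scr, 1, 3))
  proteins <- colnames(pairs$X)
  B <- matrix(0, 8, 8, dimnames = list(proteins, proteins))
  nulls <- list()
  for (o in proteins) {
    fit <- fit_pls1(pairs$X, pairs$Y[, o], ncomp = 8, output = o)
    B[o, ] <- fit$b
    nulls[[o]] <- permutation_null(pairs$X, pairs$Y[, o], n_shuffles = 300,
                                   seed = 32, ncomp = 8, output = o)
  }
  et <- significant_edges(B, nulls, level = 0.99)
  truthA <- sign(t(truth$B_true)) # source x target
  for (src in proteins) {
    for (tgt in proteins) {
      if (src == tgt) next
      if (truthA[src, tgt] != 0) {
        expect_true(et$significant[tgt, src],
                    label = sprintf("edge %s->%s recovered", src, tgt))
        expect_equal(unname(sign(B[tgt, src])), unname(truthA[src, tgt]))
      } else {
        expect_false(et$significant[tgt, src],
                     label = sprintf("no spurious %s->%s", src, tgt))
        expect_lt(abs(B[tgt, src]), 1e-8)
      }
    }
  }
})

test_that("type-I error is near 1% at the 2.58 threshold", {
  withr::local_seed(40)
  n <- 100; p <- 6; n_out <- 12
  flagged <- 0L
  for (i in seq_len(n_out)) {
    X <- scale(matrix(rnorm(n * p), n, p))[, , drop = FALSE]
    colnames(X) <- paste0("x", 1:p)
    y <- scale(rnorm(n))[, 1] # independent of X: every flag is a false positive
    fit <- fit_pls1(X, y)
    nul <- permutation_null(X, y, n_shuffles = 400, seed = 400 + i,
                            ncomp = fit$n_components)
    flagged <- flagged + sum(abs(fit$b / nul$sigma) > 2.58)
  }
  total <- n_out * p
  # binomial 99% upper bound around the nominal 1%
  expect_lte(flagged, qbinom(0.995, total, 0.01))
})
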