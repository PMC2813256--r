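#' Permutation null distribution of PLS coefficients
#'
#' Builds random models by shuffling the entries of the output vector across
#' rows (inputs fixed) and refitting a PLS model with the actual model's
#' component count for each shuffle. The per-input standard deviation of the
#' null coefficients is the scale against which actual coefficients are
#' judged (the null mean is zero by exchangeability).
#'
#' @param X,y Normalized inputs and output.
#' @param n_shuffles Number of shuffled refits (default 1000; fewer than 100
#'   triggers a warning because the sd estimate becomes unstable).
#' @param seed Integer seed.
#' @param ncomp Component count used for every null refit; defaults to the
#'   count the actual model would select.
#' @param output Optional output name.
#' @return Object of class `phos_perm_null`: `coefficients`
#'   (n_shuffles x n_inputs matrix), `sigma` (per-input sd vector),
#'   `n_shuffles`, `ncomp`, `seed`.
#' @export
permutation_null <- function(X, y, n_shuffles = 1000, seed = 1, ncomp = NULL,
                             output = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  check_number(n_shuffles, "n_shuffles", lower = 1, integerish = TRUE)
  if (n_shuffles < 100) {
    warn("Fewer than 100 shuffles gives an unstable sigma estimate.")
  }
  if (sd(y) < 1e-12) abort("Constant output: permutation null is undefined.")
  if (is.null(ncomp)) {
    eng <- pls1_engine(X, y, ncol(X))
    ncomp <- min(select_components(eng$varfrac), eng$rank)
  }
  local_seed_if(seed)

  p <- ncol(X)
  coefs <- matrix(0, n_shuffles, p, dimnames = list(NULL, colnames(X)))
  for (i in seq_len(n_shuffles)) {
    coefs[i, ] <- pls1_coef_fast(X, sample(y), ncomp)
  }
  sigma <- apply(coefs, 2, sd)

  structure(
    list(output = output %||% "y", coefficients = coefs, sigma = sigma,
         n_shuffles = n_shuffles, ncomp = ncomp, seed = seed),
    class = "phos_perm_null"
  )
}

#' @export
print.phos_perm_null <- function(x, ...) {
  cat(sprintf(
    "<phos_perm_null> output %s: %d shuffles, %d inputs, ncomp = %d\n",
    x$output, x$n_shuffles, length(x$sigma), x$ncomp
  ))
  invisible(x)
}

#' Ratio threshold for a confidence level
#'
#' The two-tailed standard-normal quantile: `qnorm(1 - (1 - level) / 2)`.
#' At 99% confidence this is 2.58 (to two decimals), the threshold applied
#' to the coefficient-to-null-sd ratio.
#'
#' @param level Confidence level in (0, 1).
#' @return The threshold `r_th`.
#' @export
#' @examples
#' round(threshold_for_confidence(0.99), 2) # 2.58
threshold_for_confidence <- function(level) {
  check_number(level, "level", lower = 0, upper = 1, open = TRUE)
  qnorm(1 - (1 - level) / 2)
}

#' Significant-edge test over all outputs
#'
#' Forms the ratio matrix `r = B / sigma` (elementwise) and flags entries
#' with `|r| > r_th` as significant and `|r| >= 0.9 * r_th` as
#' near-significant. The comparison is two-sided: inhibitory (negative)
#' coefficients are as admissible as activating ones.
#'
#' @param B Coefficient matrix, rows = outputs, cols = inputs (row `j` is the
#'   coefficient vector of output `j`'s model).
#' @param nulls Named list of [permutation_null()] objects, one per output
#'   (names matching `rownames(B)`), or a sigma matrix congruent with `B`.
#' @param level Confidence level (default 0.99).
#' @return Object of class `phos_edge_test`: `B`, `sigma`, `ratio`, `r_th`,
#'   `level`, logical masks `significant` and `near_significant`.
#' @export
significant_edges <- function(B, nulls, level = 0.99) {
  B <- as.matrix(B)
  if (is.list(nulls)) {
    if (is.null(rownames(B)) || !all(rownames(B) %in% names(nulls))) {
      abort("`nulls` must cover every output row of `B` by name.")
    }
    sigma <- t(vapply(rownames(B), function(o) nulls[[o]]$sigma,
                      numeric(ncol(B))))
    dimnames(sigma) <- dimnames(B)
  } else {
    sigma <- as.matrix(nulls)
  }
  if (!identical(dim(sigma), dim(B))) {
    abort("`B` and the sigma matrix must have congruent shapes.")
  }
  zero <- which(sigma <= 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    abort(sprintf(
      "Null sd is zero for input %s (output %s).",
      colnames(B)[zero[1, 2]] %||% zero[1, 2],
      rownames(B)[zero[1, 1]] %||% zero[1, 1]
    ))
  }

  r_th <- threshold_for_confidence(level)
  ratio <- B / sigma
  structure(
    list(
      B = B, sigma = sigma, ratio = ratio, level = level, r_th = r_th,
      significant = abs(ratio) > r_th,
      near_significant = abs(ratio) >= 0.9 * r_th
    ),
    class = "phos_edge_test"
  )
}

#' @export
print.phos_edge_test <- function(x, ...) {
  cat(sprintf(
    "<phos_edge_test> %d outputs x %d inputs, r_th = %.3f (%g%%): %d significant, %d near\n",
    nrow(x$B), ncol(x$B), x$r_th, 100 * x$level,
    sum(x$significant), sum(x$near_significant)
  ))
  invisible(x)
}
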