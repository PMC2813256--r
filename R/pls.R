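# Single-output partial least squares (PLS1), NIPALS form with X-deflation.
# The response is not deflated; for a single output the two conventions give
# identical coefficients, and X-only deflation keeps the per-component
# captured-output-variance shares additive (scores are mutually orthogonal).

# Core engine shared by the user-facing fit, the permutation null and the
# cross-validation loop. Returns weights/loadings up to the rank actually
# reached and the per-component captured output-variance fractions.
pls1_engine <- function(X, y, max_components) {
  n <- nrow(X); p <- ncol(X)
  a_max <- min(max_components, p, n - 1L)
  W <- matrix(0, p, a_max)
  P <- matrix(0, p, a_max)
  Tm <- matrix(0, n, a_max)
  q <- numeric(a_max)
  varfrac <- numeric(a_max)
  ssy <- sum(y^2)
  Xd <- X
  used <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(Xd, y)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break                       # X fully deflated / rank hit
    w <- w / wn
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12 * n) break
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(y * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    varfrac[a] <- if (ssy > 0) q_a^2 * tt / ssy else 0
    Xd <- Xd - t_a %*% t(p_a)
    used <- a
  }
  list(W = W[, seq_len(used), drop = FALSE],
       P = P[, seq_len(used), drop = FALSE],
       T = Tm[, seq_len(used), drop = FALSE],
       q = q[seq_len(used)],
       varfrac = varfrac[seq_len(used)],
       rank = used)
}

pls1_coef <- function(engine, m) {
  if (m == 0) return(numeric(nrow(engine$W)))
  W <- engine$W[, seq_len(m), drop = FALSE]
  P <- engine$P[, seq_len(m), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), engine$q[seq_len(m)]))
}

# Fast path: coefficients only, fixed component count (permutation loop).
pls1_coef_fast <- function(X, y, ncomp) {
  eng <- pls1_engine(X, y, ncomp)
  pls1_coef(eng, eng$rank)
}

#' Select the number of PLS components
#'
#' Applies the variance-share rule: a component is retained only while it
#' captures at least 5% of the total output variance captured when all
#' available components are used. Returns the largest such leading count,
#' never less than 1.
#'
#' @param varfrac Numeric vector of per-component captured output-variance
#'   fractions (of total output variance), in component order.
#' @param share Minimum share of the all-component total (default 0.05).
#' @return Integer component count.
#' @export
#' @examples
#' select_components(c(0.60, 0.30, 0.02)) # 2
select_components <- function(varfrac, share = 0.05) {
  if (length(varfrac) == 0) abort("Empty variance-fraction sequence.")
  total <- sum(varfrac)
  ok <- varfrac >= share * total
  first_bad <- which(!ok)[1]
  m <- if (is.na(first_bad)) length(varfrac) else first_bad - 1L
  max(1L, as.integer(m))
}

#' Fit a single-output PLS regression
#'
#' Deterministic NIPALS PLS1 on z-scored data (no intercept). Components are
#' computed up to `max_components` (truncated at the effective rank of `X`,
#' with a warning if truncation occurs) and the retained count is then chosen
#' by [select_components()] unless `ncomp` pins it explicitly. With all
#' components retained the coefficients coincide with the ordinary
#' least-squares solution.
#'
#' @param X Normalized input matrix (rows = cases, cols = predictors; the
#'   output protein itself is ordinarily one of the predictors, encoding
#'   self-regulation).
#' @param y Normalized output vector.
#' @param max_components Upper bound on components (default `ncol(X)`).
#' @param ncomp Optional fixed component count (used e.g. when refitting
#'   permutation-null models with the actual model's count).
#' @param output Optional output name carried in the fit.
#' @return Object of class `phos_pls`: coefficients `b` (one per input
#'   column, normalized-space units), `n_components`, per-component
#'   `varfrac`, training `r_squared`, fitted values and score/weight/loading
#'   matrices.
#' @export
fit_pls1 <- function(X, y, max_components = ncol(X), ncomp = NULL,
                     output = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("`X` and `y` disagree in length.")
  if (anyNA(X) || anyNA(y)) abort("`X` and `y` must be complete.")
  check_number(max_components, "max_components", lower = 1, integerish = TRUE)

  eng <- pls1_engine(X, y, max_components)
  if (eng$rank < min(max_components, ncol(X), nrow(X) - 1L)) {
    warn(sprintf("Component sequence truncated at rank %d.", eng$rank))
  }
  m <- if (is.null(ncomp)) {
    select_components(eng$varfrac)
  } else {
    min(as.integer(ncomp), eng$rank)
  }
  m <- min(m, eng$rank)
  b <- pls1_coef(eng, m)
  names(b) <- colnames(X)
  fitted <- drop(X %*% b)

  structure(
    list(
      output = output %||% "y",
      b = b,
      n_components = m,
      varfrac = eng$varfrac,
      r_squared = sum(eng$varfrac[seq_len(m)]),
      fitted = fitted,
      scores = eng$T, weights = eng$W, loadings = eng$P, q = eng$q,
      n = nrow(X)
    ),
    class = "phos_pls"
  )
}

#' @export
print.phos_pls <- function(x, ...) {
  cat(sprintf(
    "<phos_pls> output %s: %d component(s), R^2 = %.3f, n = %d\n",
    x$output, x$n_components, x$r_squared, x$n
  ))
  invisible(x)
}

#' Predict from a PLS fit
#'
#' Linear prediction `X_new %*% b` in normalized space (no intercept: a zero
#' input row predicts zero).
#'
#' @param object A `phos_pls` fit.
#' @param newdata Matrix with the training column order (checked by name
#'   when both are named).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.phos_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b)) {
    abort("`newdata` column count does not match the training inputs.")
  }
  if (!is.null(colnames(newdata)) && !is.null(names(object$b)) &&
      !identical(colnames(newdata), names(object$b))) {
    abort("`newdata` column order does not match the training inputs.")
  }
  drop(newdata %*% object$b)
}
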