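#' Fit a minimal (significant-predictors-only) model
#'
#' Refits an output by ordinary least squares on its significant predictors
#' only, and compares its prediction error against the full least-squares
#' model on all predictors through a two-sided F-test on the variance ratio
#' `F = sigma_r^2 / sigma_f^2` at 95% confidence. Also reports the fractions
#' of points whose reduced-model residuals fall within the full-model error
#' bands (±sigma_f, ±2 sigma_f).
#'
#' An empty `selected` set is allowed: the model is flagged `no_inputs`
#' (such a node keeps only its outgoing edges in the network) and predictions
#' are the normalized-space zero.
#'
#' @param X Normalized input matrix.
#' @param y Normalized output vector.
#' @param selected Character vector (or integer indices) of the significant
#'   predictor columns.
#' @param conf Confidence level of the similarity F-test (default 0.95).
#' @param output Optional output name.
#' @return Object of class `phos_minimal`: `coefficients` (on the selected
#'   columns), `sigma_r`, `sigma_f`, `f_statistic`, `f_pass`, band fractions
#'   `frac_1sig`/`frac_2sig`, `variance_captured`, `predicted`, `no_inputs`.
#' @export
fit_minimal <- function(X, y, selected, conf = 0.95, output = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.numeric(selected)) selected <- colnames(X)[selected]
  if (!all(selected %in% colnames(X))) {
    abort("`selected` names predictors absent from `X`.")
  }

  ls_fit <- function(M) {
    if (ncol(M) == 0) {
      list(coef = numeric(0), pred = rep(0, n))
    } else {
      b <- qr.coef(qr(M), y)
      b[is.na(b)] <- 0
      list(coef = b, pred = drop(M %*% b))
    }
  }
  full <- ls_fit(X)
  red <- ls_fit(X[, selected, drop = FALSE])

  sigma_f <- rmse(y - full$pred)
  sigma_r <- rmse(y - red$pred)
  df_r <- n - length(selected)
  df_f <- n - p
  if (df_f < 1) abort("Full model has no residual degrees of freedom.")

  f_stat <- if (sigma_f < 1e-12 && sigma_r < 1e-12) 1 else {
    (sigma_r^2) / max(sigma_f^2, 1e-300)
  }
  alpha <- 1 - conf
  f_pass <- f_stat >= qf(alpha / 2, df_r, df_f) &&
    f_stat <= qf(1 - alpha / 2, df_r, df_f)

  bands <- band_fractions(y, red$pred, max(sigma_f, 1e-12))
  ssy <- sum(y^2)
  var_captured <- if (ssy > 0) 1 - sum((y - red$pred)^2) / ssy else NA_real_

  structure(
    list(
      output = output %||% "y",
      selected = selected,
      no_inputs = length(selected) == 0,
      coefficients = red$coef,
      full_coefficients = full$coef,
      sigma_r = sigma_r, sigma_f = sigma_f,
      f_statistic = f_stat, f_conf = conf, f_pass = f_pass,
      frac_1sig = bands[["frac_1sig"]], frac_2sig = bands[["frac_2sig"]],
      variance_captured = var_captured,
      predicted = red$pred, observed = y,
      n = n
    ),
    class = "phos_minimal"
  )
}

#' @export
print.phos_minimal <- function(x, ...) {
  cat(sprintf(
    paste0("<phos_minimal> output %s: %d predictor(s), sigma_r = %.3f, ",
           "sigma_f = %.3f, F = %.3f (%s), var captured = %.1f%%\n"),
    x$output, length(x$selected), x$sigma_r, x$sigma_f, x$f_statistic,
    if (x$f_pass) "similar" else "dissimilar", 100 * x$variance_captured
  ))
  invisible(x)
}

#' Fractions of points inside the ±sigma and ±2 sigma bands
#'
#' Computed on absolute residuals `|y_obs - y_pred|`; a point exactly on a
#' band boundary counts as inside.
#'
#' @param y_obs,y_pred Observed and predicted vectors of equal length.
#' @param sigma_f Reference error (must be positive).
#' @return Named numeric vector `frac_1sig`, `frac_2sig`.
#' @export
band_fractions <- function(y_obs, y_pred, sigma_f) {
  if (length(y_obs) != length(y_pred)) {
    abort("`y_obs` and `y_pred` must have equal length.")
  }
  check_number(sigma_f, "sigma_f", lower = 0, open = TRUE, upper = Inf)
  res <- abs(y_obs - y_pred)
  c(frac_1sig = mean(res <= sigma_f), frac_2sig = mean(res <= 2 * sigma_f))
}
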