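#' Build lagged input/output matrices from a screen
#'
#' Pairs the log2 fold-change state at `t_in` (inputs, matrix `X`) with the
#' state at `t_out` (outputs, matrix `Y`), one row per experiment-replicate:
#' replicates are treated as separate conditions so experiments with more
#' replicates carry proportionally more weight. The t = 0 baseline never
#' enters (it is identically 1, i.e. log2 = 0). Rows with any missing value
#' at either time are dropped with a message.
#'
#' @param screen A screen tibble ([as_screen()] dialect).
#' @param t_in,t_out Input and output times in minutes; `t_in < t_out` and
#'   both must be on the screen's grid. The default pair (1, 3) restricts the
#'   fit to the early response, before receptor desensitisation makes
#'   dephosphorylation dominate.
#' @return An object of class `phos_lag_pairs`: list with matrices `X`, `Y`
#'   (rows = experiment-replicates, cols = proteins, log2 units), row
#'   annotation tibble `info` (`experiment_id`, `ligands`, `replicate`),
#'   `t_in`, `t_out`, `normalized` flag and (after [zscore_normalize()])
#'   the per-column `stats`.
#' @export
build_lag_pairs <- function(screen, t_in = 1, t_out = 3) {
  screen <- as_screen(screen)
  if (t_in >= t_out) abort("`t_in` must be strictly less than `t_out`.")
  times <- unique(screen$time_min)
  if (!all(c(t_in, t_out) %in% times)) {
    abort(sprintf("Times %g and %g must both be on the screen grid (%s).",
                  t_in, t_out, paste(sort(times), collapse = ", ")))
  }

  wide_at <- function(t) {
    screen |>
      dplyr::filter(.data$time_min == t) |>
      dplyr::mutate(log2fc = log2(.data$fold_change)) |>
      tidyr::pivot_wider(
        id_cols = c("experiment_id", "ligands", "replicate"),
        names_from = "protein", values_from = "log2fc"
      ) |>
      dplyr::arrange(.data$experiment_id, .data$replicate)
  }
  win <- wide_at(t_in)
  wout <- wide_at(t_out)
  keys <- c("experiment_id", "ligands", "replicate")
  merged <- dplyr::inner_join(win, wout, by = keys, suffix = c(".in", ".out"))

  proteins <- sort(setdiff(names(win), keys))
  X <- as.matrix(merged[paste0(proteins, ".in")])
  Y <- as.matrix(merged[paste0(proteins, ".out")])
  colnames(X) <- colnames(Y) <- proteins

  complete <- stats::complete.cases(X) & stats::complete.cases(Y)
  n_drop <- sum(!complete) + (nrow(win) - nrow(merged)) +
    (nrow(wout) - nrow(merged))
  if (n_drop > 0) {
    inform(sprintf("Dropped %d incomplete experiment-replicate row(s).", n_drop))
  }

  structure(
    list(
      X = X[complete, , drop = FALSE],
      Y = Y[complete, , drop = FALSE],
      info = merged[complete, keys],
      t_in = t_in, t_out = t_out,
      normalized = FALSE, stats = NULL
    ),
    class = "phos_lag_pairs"
  )
}

#' @export
print.phos_lag_pairs <- function(x, ...) {
  cat(sprintf(
    "<phos_lag_pairs> %d rows x %d proteins, t %g -> %g min%s\n",
    nrow(x$X), ncol(x$X), x$t_in, x$t_out,
    if (x$normalized) " (z-scored)" else ""
  ))
  invisible(x)
}

#' Z-score the lagged matrices
#'
#' Centers and scales every input and output column to mean 0, sd 1 (each
#' matrix with its own per-protein statistics, which are retained for the
#' inverse transform). Zero-variance columns are an error naming the protein.
#'
#' @param pairs A [build_lag_pairs()] object.
#' @return The normalized `phos_lag_pairs`, with `stats` populated.
#' @export
zscore_normalize <- function(pairs) {
  stopifnot(inherits(pairs, "phos_lag_pairs"))
  if (pairs$normalized) return(pairs)
  zstats <- function(M, which) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, sd)
    flat <- sdv < 1e-12
    if (any(flat)) {
      abort(sprintf("Zero-variance %s column(s): %s.", which,
                    paste(colnames(M)[flat], collapse = ", ")))
    }
    list(mean = mu, sd = sdv)
  }
  sx <- zstats(pairs$X, "input")
  sy <- zstats(pairs$Y, "output")
  pairs$X <- scale(pairs$X, center = sx$mean, scale = sx$sd)
  pairs$Y <- scale(pairs$Y, center = sy$mean, scale = sy$sd)
  attr(pairs$X, "scaled:center") <- attr(pairs$X, "scaled:scale") <- NULL
  attr(pairs$Y, "scaled:center") <- attr(pairs$Y, "scaled:scale") <- NULL
  pairs$stats <- list(x = sx, y = sy)
  pairs$normalized <- TRUE
  pairs
}

#' Invert the z-score transform
#' @param pairs A normalized `phos_lag_pairs`.
#' @return The pairs on the original log2 scale.
#' @export
denormalize <- function(pairs) {
  stopifnot(inherits(pairs, "phos_lag_pairs"))
  if (!pairs$normalized) return(pairs)
  s <- pairs$stats
  pairs$X <- sweep(sweep(pairs$X, 2, s$x$sd, "*"), 2, s$x$mean, "+")
  pairs$Y <- sweep(sweep(pairs$Y, 2, s$y$sd, "*"), 2, s$y$mean, "+")
  pairs$normalized <- FALSE
  pairs$stats <- NULL
  pairs
}

#' Input-output (dynamic) correlation matrix
#'
#' Pearson correlation of every input protein at `t_in` with every output
#' protein at `t_out` — the lagged analogue of a correlation heat map, where
#' a strong diagonal indicates self-regulation and off-diagonal structure
#' suggests crosstalk.
#'
#' @param pairs A `phos_lag_pairs` object with at least 3 rows.
#' @return Matrix (inputs x outputs) of class `phos_dyncor`.
#' @export
dynamic_correlation <- function(pairs) {
  stopifnot(inherits(pairs, "phos_lag_pairs"))
  if (nrow(pairs$X) < 3) abort("Need at least 3 rows to correlate.")
  cm <- cor(pairs$X, pairs$Y)
  structure(cm, class = c("phos_dyncor", class(cm)),
            t_in = pairs$t_in, t_out = pairs$t_out)
}

#' Write a correlation matrix as labelled TSV
#' @param cm A [dynamic_correlation()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(cm, path) {
  df <- tibble::as_tibble(unclass(cm), rownames = "input")
  readr::write_tsv(df, path)
  invisible(path)
}
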