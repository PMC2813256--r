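# broom-style tidiers: tidy() gives the per-term/per-edge table, glance()
# the one-row model summary.

#' @export
tidy.phos_pls <- function(x, ...) {
  tibble::tibble(
    output = x$output,
    term = names(x$b) %||% paste0("x", seq_along(x$b)),
    estimate = unname(x$b)
  )
}

#' @export
glance.phos_pls <- function(x, ...) {
  tibble::tibble(
    output = x$output,
    r.squared = x$r_squared,
    n_components = x$n_components,
    nobs = x$n
  )
}

#' @export
tidy.phos_validation <- function(x, ...) {
  tibble::tibble(
    output = x$output,
    k = x$k,
    mean_test_sse = mean(x$test_sse),
    mean_train_sse = mean(x$train_sse),
    f_statistic = x$f_statistic,
    f_probability = x$f_probability,
    p_random = x$p_random,
    r_squared = x$r_squared,
    n_components = x$n_components,
    pass_train_test = x$pass_train_test,
    pass_random = x$pass_random,
    pass_variance = x$pass_variance,
    accepted = x$accepted
  )
}

#' @export
glance.phos_validation <- function(x, ...) tidy(x)[
  c("output", "f_statistic", "f_probability", "p_random", "r_squared",
    "accepted")
]

#' @export
tidy.phos_perm_null <- function(x, ...) {
  tibble::tibble(
    output = x$output,
    input = colnames(x$coefficients) %||% paste0("x", seq_along(x$sigma)),
    sigma = unname(x$sigma),
    null_mean = unname(colMeans(x$coefficients))
  )
}

#' @export
tidy.phos_edge_test <- function(x, ...) {
  tibble::tibble(
    output = rep(rownames(x$B), ncol(x$B)),
    input = rep(colnames(x$B), each = nrow(x$B)),
    coefficient = as.vector(x$B),
    sigma = as.vector(x$sigma),
    ratio = as.vector(x$ratio),
    significant = as.vector(x$significant),
    near_significant = as.vector(x$near_significant)
  ) |>
    dplyr::arrange(.data$output, .data$input)
}

#' @export
glance.phos_edge_test <- function(x, ...) {
  tibble::tibble(
    level = x$level, r_th = x$r_th,
    n_significant = sum(x$significant),
    n_near_significant = sum(x$near_significant)
  )
}

#' @export
tidy.phos_minimal <- function(x, ...) {
  tibble::tibble(
    output = x$output,
    term = names(x$coefficients) %||% character(0),
    estimate = unname(x$coefficients)
  )
}

#' @export
glance.phos_minimal <- function(x, ...) {
  tibble::tibble(
    output = x$output,
    n_predictors = length(x$selected),
    sigma_r = x$sigma_r, sigma_f = x$sigma_f,
    f_statistic = x$f_statistic, f_pass = x$f_pass,
    variance_captured = x$variance_captured,
    frac_1sig = x$frac_1sig, frac_2sig = x$frac_2sig,
    nobs = x$n
  )
}

#' @export
tidy.phos_network <- function(x, ...) {
  idx <- which(x$A != 0, arr.ind = TRUE)
  tibble::tibble(
    source = x$nodes[idx[, 1]],
    target = x$nodes[idx[, 2]],
    sign = as.integer(x$A[idx]),
    confidence = x$confidence[idx]
  ) |>
    dplyr::arrange(.data$source, .data$target)
}

#' @export
glance.phos_network <- function(x, ...) {
  gm <- global_metrics(x)
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = sum(x$A != 0),
    n_activating = sum(x$A > 0),
    n_inhibitory = sum(x$A < 0),
    avg_degree = gm$avg_degree,
    avg_shortest_path = gm$avg_shortest_path
  )
}

#' @export
tidy.phos_paths <- function(x, ...) {
  if (length(x$paths) == 0) {
    return(tibble::tibble(source = character(0), target = character(0),
                          path = character(0), length = integer(0)))
  }
  tibble::tibble(
    source = x$source, target = x$target,
    path = vapply(seq_along(x$paths), function(i) {
      p <- x$paths[[i]]; s <- x$signs[[i]]
      paste0(p[1], paste0(ifelse(s > 0, " -> ", " -| "), p[-1],
                          collapse = ""))
    }, character(1)),
    length = x$lengths
  )
}

#' @export
glance.phos_paths <- function(x, ...) path_metrics(x)

#' @export
tidy.phos_consistency <- function(x, ...) {
  tibble::as_tibble(x$cases)
}

#' @export
glance.phos_consistency <- function(x, ...) {
  cnt <- as.list(x$counts)
  tibble::tibble(
    target = x$target,
    path1_source = x$predecessors[1], path2_source = x$predecessors[2],
    none = cnt$none, path1 = cnt$path1, path2 = cnt$path2, both = cnt$both,
    n = nrow(x$cases)
  )
}

#' @export
tidy.phos_extrapolation <- function(x, ...) x$predictions

#' @export
glance.phos_extrapolation <- function(x, ...) {
  if (is.null(x$bands)) {
    return(tibble::tibble(t_start = x$t_start, t_end = x$t_end,
                          frac_1sig = NA_real_, frac_2sig = NA_real_))
  }
  tibble::tibble(
    t_start = x$t_start, t_end = x$t_end,
    frac_1sig = mean(x$bands$frac_1sig),
    frac_2sig = mean(x$bands$frac_2sig)
  )
}

#' @export
tidy.phos_dyncor <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    input = rep(rownames(m), ncol(m)),
    output = rep(colnames(m), each = nrow(m)),
    correlation = as.vector(m)
  )
}
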