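# ggplot2 autoplot() methods, one per result type. These return plot
# objects; nothing is drawn on file by the pipeline itself.

#' @export
autoplot.phos_dyncor <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$output, y = .data$input,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(
      title = "Lagged input-output correlation",
      x = sprintf("output (t = %g min)", attr(object, "t_out")),
      y = sprintf("input (t = %g min)", attr(object, "t_in"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.phos_edge_test <- function(object, outputs = NULL, ...) {
  df <- tidy(object)
  if (!is.null(outputs)) df <- df[df$output %in% outputs, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$input, y = .data$ratio,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$r_th,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~output) +
    ggplot2::labs(y = "coefficient / null sd (z-score)", x = "input",
                  title = sprintf("Edge significance at %g%% confidence",
                                  100 * object$level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# shared observed-vs-predicted scatter with error bands
plot_obs_pred <- function(df, sigma_f, title) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = c(-1, 1) * sigma_f,
                         linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = c(-2, 2) * sigma_f,
                         linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "observed (log2 fold change)",
                  y = "predicted (log2 fold change)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phos_minimal <- function(object, ...) {
  df <- tibble::tibble(observed = object$observed,
                       predicted = object$predicted)
  plot_obs_pred(df, object$sigma_f,
                sprintf("Minimal model for %s (bands: +/-sigma_f, +/-2 sigma_f)",
                        object$output))
}

#' @export
autoplot.phos_extrapolation <- function(object, protein = NULL, ...) {
  df <- object$predictions[!is.na(object$predictions$observed), ]
  if (!is.null(protein)) {
    df <- df[df$protein %in% protein, ]
    sf <- mean(object$sigma_f[protein], na.rm = TRUE)
  } else {
    df <- df[df$protein %in% object$modeled, ]
    sf <- mean(object$sigma_f, na.rm = TRUE)
  }
  plot_obs_pred(df, sf,
                sprintf("Extrapolation %g -> %g min", object$t_start,
                        object$t_end))
}

#' @export
autoplot.phos_consistency <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$counts))
  names(df) <- c("class", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("Edge consistency for %s (path 1: %s, path 2: %s)",
                      object$target, object$predecessors[1],
                      object$predecessors[2]),
      x = "consistent path(s)", y = "experiment-replicates"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phos_network <- function(object, ...) {
  nodes <- object$nodes
  n <- length(nodes)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  layout <- tibble::tibble(node = nodes, x = cos(ang), y = sin(ang))
  edges <- tidy(object)
  edges <- dplyr::left_join(edges, layout, by = c(source = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c(target = "node")) |>
    dplyr::mutate(sign_lab = ifelse(.data$sign > 0, "activation",
                                    "inhibition"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, colour = .data$sign_lab,
                   linewidth = sqrt(.data$confidence)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      alpha = 0.7
    ) +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node)) +
    ggplot2::scale_colour_manual(values = c(activation = "black",
                                            inhibition = "red")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}
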