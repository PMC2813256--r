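#' Classify experiments by edge consistency for an in-degree-2 node
#'
#' For a target node with exactly two incoming edges, every
#' experiment-replicate is classified by which of the two edges is
#' sign-consistent with the data: an edge i -> j is consistent when
#' `sign(node i) * sign(edge i -> j) = sign(node j)`, with node signs taken
#' from the log2 fold-change at `t_in` (sources) and `t_out` (target).
#' Classes are `"none"`, `"path1"` (first predecessor's edge only),
#' `"path2"`, `"both"`. A log2 value whose magnitude is inside `dead_zone`
#' has sign 0 and is consistent with neither sign.
#'
#' @param net A `phos_network`.
#' @param target Node with in-degree exactly 2 (use per-edge analysis
#'   otherwise).
#' @param screen The screen tibble the network was inferred from.
#' @param t_in,t_out Times (minutes) at which source and target signs are
#'   read.
#' @param dead_zone Magnitude below which a log2 value counts as zero
#'   (default 0: raw sign).
#' @return Object of class `phos_consistency`: `cases` tibble (one row per
#'   experiment-replicate with source/target signs, per-edge consistency and
#'   `class`), `counts` per class, the predecessor names and edge signs.
#' @export
classify_experiments <- function(net, target, screen, t_in = 1, t_out = 3,
                                 dead_zone = 0) {
  stopifnot(inherits(net, "phos_network"))
  screen <- as_screen(screen)
  if (!target %in% net$nodes) abort(sprintf("Unknown node '%s'.", target))
  preds <- net$nodes[net$A[, target] != 0]
  if (length(preds) != 2) {
    abort(sprintf(
      "Node '%s' has in-degree %d, not 2; the four-way classification needs exactly two incoming edges.",
      target, length(preds)
    ))
  }
  edge_signs <- net$A[preds, target]

  value_at <- function(prot, t) {
    screen |>
      dplyr::filter(.data$protein == prot, .data$time_min == t) |>
      dplyr::transmute(.data$experiment_id, .data$ligands, .data$replicate,
                       log2fc = log2(.data$fold_change))
  }
  keys <- c("experiment_id", "ligands", "replicate")
  tab <- value_at(preds[1], t_in) |>
    dplyr::rename(src1 = "log2fc") |>
    dplyr::inner_join(value_at(preds[2], t_in) |> dplyr::rename(src2 = "log2fc"),
                      by = keys) |>
    dplyr::inner_join(value_at(target, t_out) |> dplyr::rename(tgt = "log2fc"),
                      by = keys)

  s1 <- signum(tab$src1, dead_zone)
  s2 <- signum(tab$src2, dead_zone)
  st <- signum(tab$tgt, dead_zone)
  c1 <- s1 != 0 & st != 0 & (s1 * edge_signs[1] == st)
  c2 <- s2 != 0 & st != 0 & (s2 * edge_signs[2] == st)
  cls <- dplyr::case_when(
    c1 & c2 ~ "both",
    c1 & !c2 ~ "path1",
    !c1 & c2 ~ "path2",
    .default = "none"
  )
  cases <- tab |>
    dplyr::mutate(
      sign1 = s1, sign2 = s2, sign_target = st,
      edge1_consistent = c1, edge2_consistent = c2,
      class = factor(cls, levels = c("none", "path1", "path2", "both"))
    )
  structure(
    list(
      target = target, predecessors = preds, edge_signs = edge_signs,
      t_in = t_in, t_out = t_out, dead_zone = dead_zone,
      cases = cases,
      counts = table(cases$class)
    ),
    class = "phos_consistency"
  )
}

#' @export
print.phos_consistency <- function(x, ...) {
  cat(sprintf(
    "<phos_consistency> %s (edges: %s %s, %s %s), %d cases\n",
    x$target,
    x$predecessors[1], if (x$edge_signs[1] > 0) "+" else "-",
    x$predecessors[2], if (x$edge_signs[2] > 0) "+" else "-",
    nrow(x$cases)
  ))
  print(x$counts)
  invisible(x)
}

#' Per-ligand distribution of consistency classes
#'
#' Counts classified experiment-replicates per ligand and class; a
#' dual-ligand experiment is added to both of its ligands.
#'
#' @param report A [classify_experiments()] report.
#' @return Tibble with `ligand`, `class`, `n` (all classes present for every
#'   ligand, zero-filled).
#' @export
ligand_distribution <- function(report) {
  stopifnot(inherits(report, "phos_consistency"))
  report$cases |>
    dplyr::mutate(ligand = strsplit(.data$ligands, "+", fixed = TRUE)) |>
    tidyr::unnest("ligand") |>
    dplyr::count(.data$ligand, .data$class, .drop = FALSE) |>
    dplyr::arrange(.data$ligand, .data$class)
}

#' Heat-map matrix of the experiments behind a consistency class
#'
#' The underlying matrix of a class panel: one row per experiment-replicate
#' in the class, columns = the two source nodes (log2 at `t_in`) and the
#' target (log2 at `t_out`).
#'
#' @param report A [classify_experiments()] report.
#' @param class One of `"none"`, `"path1"`, `"path2"`, `"both"`.
#' @return Tibble with `experiment_id`, `ligands`, `replicate` and one
#'   column per node.
#' @export
consistency_matrix <- function(report,
                               class = c("none", "path1", "path2", "both")) {
  stopifnot(inherits(report, "phos_consistency"))
  class <- match.arg(class)
  sel <- report$cases[report$cases$class == class, ]
  out <- sel[c("experiment_id", "ligands", "replicate",
               "src1", "src2", "tgt")]
  names(out)[4:6] <- c(report$predecessors, report$target)
  tibble::as_tibble(out)
}
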