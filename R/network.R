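#' Assemble the signed directed network
#'
#' Builds the signed adjacency `A = sign(t(B))` restricted to significant
#' coefficients of accepted output models: `A[i, j]` is the sign of the edge
#' i -> j, nonzero only when output `j`'s model was accepted and input `i`
#' crossed the significance threshold. Self terms, although predictors in
#' the regressions, are excluded from the graph (no self-loops). Each edge
#' carries its |ratio| as confidence.
#'
#' @param edge_test A [significant_edges()] object (single confidence level).
#' @param accepted Character vector of accepted output names (default: all
#'   outputs of `edge_test`).
#' @return Object of class `phos_network`: `nodes`, signed adjacency `A`
#'   (entries -1/0/+1, `A[i, j]` = sign of i -> j), `confidence` matrix
#'   (|ratio| where an edge exists, 0 elsewhere), the full `ratio` matrix
#'   (outputs x inputs), `r_th`, `accepted`.
#' @export
assemble_network <- function(edge_test, accepted = NULL) {
  stopifnot(inherits(edge_test, "phos_edge_test"))
  outputs <- rownames(edge_test$B)
  inputs <- colnames(edge_test$B)
  nodes <- sort(union(outputs, inputs))
  accepted <- accepted %||% outputs
  n <- length(nodes)

  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  conf <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (j in outputs) {
    if (!j %in% accepted) next
    for (i in inputs) {
      if (i == j) next
      if (edge_test$significant[j, i]) {
        A[i, j] <- as.integer(sign(edge_test$B[j, i]))
        conf[i, j] <- abs(edge_test$ratio[j, i])
      }
    }
  }
  structure(
    list(nodes = nodes, A = A, confidence = conf,
         ratio = edge_test$ratio, r_th = edge_test$r_th,
         accepted = intersect(outputs, accepted)),
    class = "phos_network"
  )
}

#' Construct a network directly from a signed edge list
#'
#' Convenience constructor used for worked examples and round-tripping
#' exported edge lists.
#'
#' @param edges Data frame with columns `source`, `target`, `sign` and
#'   optionally `confidence`.
#' @param nodes Optional node universe (default: nodes appearing in `edges`).
#' @return A `phos_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  nodes <- sort(unique(c(nodes, edges$source, edges$target)))
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  conf <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(edges$source, edges$target)] <- as.integer(sign(edges$sign))
  conf[cbind(edges$source, edges$target)] <-
    if ("confidence" %in% names(edges)) edges$confidence else NA_real_
  structure(
    list(nodes = nodes, A = A, confidence = conf,
         ratio = NULL, r_th = NA_real_, accepted = nodes),
    class = "phos_network"
  )
}

#' @export
print.phos_network <- function(x, ...) {
  cat(sprintf(
    "<phos_network> %d nodes, %d edges (%d activating, %d inhibitory)\n",
    length(x$nodes), sum(x$A != 0), sum(x$A > 0), sum(x$A < 0)
  ))
  invisible(x)
}

#' Merge variant nodes (e.g. protein isoforms) into single nodes
#'
#' Averages the corresponding rows and columns of the significance-ratio
#' matrix across each group, then re-thresholds and re-signs the merged
#' entries. If group members that are individually significant disagree in
#' sign towards the same counterpart, that merged edge is ambiguous: it is
#' dropped and the conflict logged (warning + `conflicts` attribute).
#'
#' @param net A `phos_network` built by [assemble_network()] (the full ratio
#'   matrix is required).
#' @param groups Named list of character vectors; each element merges its
#'   member nodes into a node named after the element. Groups must be
#'   disjoint.
#' @return A merged `phos_network` (with a `conflicts` field listing dropped
#'   ambiguous edges).
#' @export
merge_variant_nodes <- function(net, groups) {
  stopifnot(inherits(net, "phos_network"))
  if (is.null(net$ratio)) {
    abort("Merging needs the full ratio matrix (network built from an edge test).")
  }
  members <- unlist(groups)
  if (anyDuplicated(members)) abort("Groups must be disjoint.")
  if (!all(members %in% net$nodes)) {
    abort("Group member(s) absent from the network.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list.")
  }

  ratio <- net$ratio # outputs x inputs
  outputs <- rownames(ratio); inputs <- colnames(ratio)

  merge_axis <- function(M, margin, groups) {
    # average grouped rows (margin 1) or columns (margin 2)
    for (g in names(groups)) {
      mem <- intersect(groups[[g]], if (margin == 1) rownames(M) else colnames(M))
      if (length(mem) == 0) next
      if (margin == 1) {
        avg <- colMeans(M[mem, , drop = FALSE])
        M <- M[setdiff(rownames(M), mem), , drop = FALSE]
        M <- rbind(M, matrix(avg, 1, dimnames = list(g, colnames(M))))
      } else {
        avg <- rowMeans(M[, mem, drop = FALSE])
        M <- M[, setdiff(colnames(M), mem), drop = FALSE]
        M <- cbind(M, matrix(avg, ncol = 1, dimnames = list(rownames(M), g)))
      }
    }
    M
  }

  merged_ratio <- merge_axis(merge_axis(ratio, 1, groups), 2, groups)

  # sign-conflict scan: significant members disagreeing towards a counterpart
  conflicts <- list()
  sig <- abs(ratio) > net$r_th
  for (g in names(groups)) {
    mem <- groups[[g]]
    for (ax in 1:2) {
      counterparts <- if (ax == 1) inputs else outputs
      for (cp in counterparts) {
        vals <- if (ax == 1) ratio[intersect(mem, outputs), cp]
                else ratio[cp, intersect(mem, inputs)]
        sigs <- if (ax == 1) sig[intersect(mem, outputs), cp]
                else sig[cp, intersect(mem, inputs)]
        s <- sign(vals[sigs])
        if (length(unique(s[s != 0])) > 1) {
          conflicts[[length(conflicts) + 1]] <- list(
            group = g, counterpart = cp,
            direction = if (ax == 1) "incoming" else "outgoing"
          )
        }
      }
    }
  }

  # map accepted outputs: a merged output is accepted iff all members were
  node_map <- setNames(rownames(merged_ratio), rownames(merged_ratio))
  acc <- net$accepted
  merged_accepted <- unique(vapply(rownames(merged_ratio), function(o) {
    mem <- if (o %in% names(groups)) groups[[o]] else o
    if (all(mem %in% acc)) o else NA_character_
  }, character(1)))
  merged_accepted <- merged_accepted[!is.na(merged_accepted)]

  et <- structure(
    list(B = merged_ratio, sigma = merged_ratio * 0 + 1, ratio = merged_ratio,
         level = NA_real_, r_th = net$r_th,
         significant = abs(merged_ratio) > net$r_th,
         near_significant = abs(merged_ratio) >= 0.9 * net$r_th),
    class = "phos_edge_test"
  )
  out <- assemble_network(et, accepted = merged_accepted)

  if (length(conflicts) > 0) {
    for (cf in conflicts) {
      warn(sprintf("Sign conflict merging '%s' (%s edge with %s): edge dropped.",
                   cf$group, cf$direction, cf$counterpart))
      if (cf$direction == "incoming") {
        cp <- if (cf$counterpart %in% names(groups)) cf$counterpart else cf$counterpart
        if (cp %in% rownames(out$A) && cf$group %in% colnames(out$A)) {
          out$A[cp, cf$group] <- 0L
          out$confidence[cp, cf$group] <- 0
        }
      } else {
        if (cf$group %in% rownames(out$A) && cf$counterpart %in% colnames(out$A)) {
          out$A[cf$group, cf$counterpart] <- 0L
          out$confidence[cf$group, cf$counterpart] <- 0
        }
      }
    }
  }
  out$conflicts <- conflicts
  out$merged_groups <- groups
  out
}

#' Enumerate all simple directed paths between two nodes
#'
#' Depth-first search over the signed digraph; paths revisit no node, and
#' the report lists them in lexicographic order of their node sequences so
#' results are reproducible.
#'
#' @param net A `phos_network`.
#' @param source,target Distinct node names.
#' @return Object of class `phos_paths`: `paths` (list of node vectors),
#'   `signs` (list of per-edge sign vectors), `lengths` (edge counts),
#'   `source`, `target`.
#' @export
enumerate_paths <- function(net, source, target) {
  stopifnot(inherits(net, "phos_network"))
  if (!all(c(source, target) %in% net$nodes)) {
    abort(sprintf("Unknown node(s): %s.",
                  paste(setdiff(c(source, target), net$nodes), collapse = ", ")))
  }
  if (source == target) abort("`source` and `target` must differ.")

  A <- net$A
  nodes <- net$nodes
  # successor lists in lexicographic order => DFS emits sorted paths
  succ <- lapply(nodes, function(v) nodes[A[v, ] != 0])
  names(succ) <- nodes

  paths <- list()
  visited <- setNames(logical(length(nodes)), nodes)
  stack <- character(0)

  dfs <- function(v) {
    visited[[v]] <<- TRUE
    stack <<- c(stack, v)
    if (v == target) {
      paths[[length(paths) + 1]] <<- stack
    } else {
      for (w in succ[[v]]) if (!visited[[w]]) dfs(w)
    }
    stack <<- stack[-length(stack)]
    visited[[v]] <<- FALSE
  }
  dfs(source)

  signs <- lapply(paths, function(p) {
    if (length(p) < 2) integer(0)
    else A[cbind(p[-length(p)], p[-1])]
  })
  structure(
    list(paths = paths, signs = signs,
         lengths = vapply(paths, length, integer(1)) - 1L,
         source = source, target = target),
    class = "phos_paths"
  )
}

#' @export
print.phos_paths <- function(x, ...) {
  cat(sprintf("<phos_paths> %s -> %s: %d path(s)\n",
              x$source, x$target, length(x$paths)))
  for (i in seq_along(x$paths)) {
    p <- x$paths[[i]]
    s <- x$signs[[i]]
    edge_glyph <- ifelse(s > 0, " -> ", " -| ")
    cat("  ", paste0(p[1], paste0(edge_glyph, p[-1], collapse = "")), "\n",
        sep = "")
  }
  invisible(x)
}

#' Path-count and path-length metrics for a node pair
#'
#' @param report An [enumerate_paths()] report.
#' @return Tibble with `count`, `mpl` (minimum path length), `apl` (average
#'   path length, arithmetic mean of edge counts); `mpl`/`apl` are `NA` when
#'   no path exists.
#' @export
path_metrics <- function(report) {
  stopifnot(inherits(report, "phos_paths"))
  if (length(report$lengths) == 0) {
    return(tibble::tibble(source = report$source, target = report$target,
                          count = 0L, mpl = NA_real_, apl = NA_real_))
  }
  tibble::tibble(
    source = report$source, target = report$target,
    count = length(report$lengths),
    mpl = min(report$lengths),
    apl = mean(report$lengths)
  )
}

#' Whole-network graph metrics
#'
#' Average shortest-path length over ordered node pairs joined by at least
#' one directed path (BFS distances), and the average node degree
#' (in-degree + out-degree).
#'
#' @param net A `phos_network`.
#' @return Tibble with `avg_shortest_path` (`NA` if no pair is reachable)
#'   and `avg_degree`.
#' @export
global_metrics <- function(net) {
  stopifnot(inherits(net, "phos_network"))
  A <- net$A != 0
  n <- length(net$nodes)
  dists <- c()
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ])) {
          if (is.na(d[w])) { d[w] <- d[v] + 1L; nxt <- c(nxt, w) }
        }
      }
      frontier <- nxt
    }
    dists <- c(dists, d[-s][!is.na(d[-s])])
  }
  tibble::tibble(
    avg_shortest_path = if (length(dists) > 0) mean(dists) else NA_real_,
    avg_degree = mean(rowSums(A) + colSums(A))
  )
}

#' Export a network to disk
#'
#' Formats: `"tsv"` (columns source, target, sign, confidence,
#' sqrt_confidence — the square-root scale is the conventional line-thickness
#' scale for confidence), `"dot"` (Graphviz; activating edges use normal
#' arrowheads, inhibitory ones blunt tees) and `"graphml"` (via igraph).
#'
#' @param net A `phos_network`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"dot"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "dot", "graphml")) {
  stopifnot(inherits(net, "phos_network"))
  format <- match.arg(format)
  edges <- tidy(net)
  if (format == "tsv") {
    edges$sqrt_confidence <- sqrt(edges$confidence)
    readr::write_tsv(edges, path)
  } else if (format == "dot") {
    lines <- c("digraph phosnet {",
               sprintf("  \"%s\";", net$nodes),
               sprintf(
                 "  \"%s\" -> \"%s\" [arrowhead=%s, penwidth=%.3f];",
                 edges$source, edges$target,
                 ifelse(edges$sign > 0, "normal", "tee"),
                 pmax(sqrt(edges$confidence), 0.5)
               ),
               "}")
    writeLines(lines, path)
  } else {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      abort("GraphML export requires the igraph package.")
    }
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge-list TSV written by [export_network()]
#' @param path TSV path.
#' @param nodes Optional node universe (to preserve isolated nodes).
#' @return A `phos_network`.
#' @export
read_network_tsv <- function(path, nodes = NULL) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  network_from_edges(edges, nodes = nodes)
}
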