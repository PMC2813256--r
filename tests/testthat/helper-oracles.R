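# Shared fixtures and independent oracles.

# The worked-example subgraph: the 9 signed edges appearing in the published
# path list between P38 and GSKa/b.
table2_edges <- function() {
  tibble::tribble(
    ~source,   ~target,  ~sign,
    "P38",     "AKT",     1,
    "AKT",     "GSKa/b",  1,
    "P38",     "ERM",    -1,
    "ERM",     "AKT",    -1,
    "P38",     "GSKa/b",  1,
    "P38",     "PKCM",    1,
    "PKCM",    "ST1A/B", -1,
    "ST1A/B",  "PKCD",    1,
    "PKCD",    "ERM",     1
  )
}

table2_network <- function() network_from_edges(table2_edges())

# Brute-force simple-path oracle: enumerate every ordered arrangement of
# intermediate nodes and keep sequences whose consecutive edges all exist.
# Independent of the package's DFS.
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

brute_force_paths <- function(net, source, target) {
  A <- net$A
  inter <- setdiff(net$nodes, c(source, target))
  found <- list()
  for (k in 0:length(inter)) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(inter, k, simplify = FALSE)
    for (ss in subsets) {
      for (mid in all_perms(ss)) {
        seqn <- c(source, mid, target)
        edges <- cbind(seqn[-length(seqn)], seqn[-1])
        if (all(A[edges] != 0)) found[[length(found) + 1]] <- seqn
      }
    }
  }
  found
}

path_key <- function(paths) sort(vapply(paths, paste, character(1),
                                        collapse = ">"))

# Random signed digraph on n nodes (no self-loops).
random_signed_digraph <- function(n, density = 0.3) {
  nodes <- LETTERS[seq_len(n)]
  A <- matrix(sample(c(-1L, 1L, 0L), n * n, replace = TRUE,
                     prob = c(density / 2, density / 2, 1 - density)),
              n, n, dimnames = list(nodes, nodes))
  diag(A) <- 0L
  net <- network_from_edges(
    tibble::tibble(
      source = nodes[which(A != 0, arr.ind = TRUE)[, 1]],
      target = nodes[which(A != 0, arr.ind = TRUE)[, 2]],
      sign = A[A != 0]
    ),
    nodes = nodes
  )
  net
}

# Least-squares oracle via the normal equations (independent of qr/PLS).
ols_coef <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# A small deterministic screen for IO tests: 2 proteins, 2 experiments.
toy_screen <- function() {
  grid <- expand.grid(
    experiment_id = c("E0001", "E0002"),
    replicate = 1:2,
    time_min = c(0, 1, 3),
    protein = c("PPA", "PPB"),
    stringsAsFactors = FALSE
  )
  attr(grid, "out.attrs") <- NULL
  grid$ligands <- ifelse(grid$experiment_id == "E0001", "LPS", "LPS+PGE")
  grid$fold_change <- ifelse(
    grid$time_min == 0, 1,
    2^(0.3 * grid$time_min * ifelse(grid$protein == "PPA", 1, -0.5))
  )
  as_screen(tibble::as_tibble(grid)[
    c("experiment_id", "ligands", "replicate", "time_min", "protein",
      "fold_change")
  ])
}
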