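test_that("assembly keeps only significant edges into accepted outputs", {
  prot <- c("AKT", "GSK", "P38")
  B <- matrix(0, 3, 3, dimnames = list(prot, prot))
  B["GSK", "P38"] <- 0.5   # P38 -> GSK, positive
  B["AKT", "P38"] <- -0.4  # P38 -| AKT
  B["AKT", "AKT"] <- 0.9   # self term: must not become a loop
  sigma <- matrix(0.1, 3, 3, dimnames = dimnames(B))
  et <- significant_edges(B, sigma, level = 0.99)

  net <- assemble_network(et)
  expect_equal(net$A["P38", "GSK"], 1L)
  expect_equal(net$A["P38", "AKT"], -1L)
  expect_equal(sum(diag(net$A) != 0), 0)
  expect_equal(sum(net$A != 0), 2)
  expect_true(all(net$confidence[net$A != 0] > net$r_th))

  # a rejected output keeps outgoing edges but loses its inputs
  net2 <- assemble_network(et, accepted = c("GSK"))
  expect_equal(sum(net2$A[, "AKT"] != 0), 0)
  expect_equal(net2$A["P38", "GSK"], 1L)

  z <- significant_edges(B * 0 + 0.001, sigma, level = 0.99)
  expect_equal(sum(assemble_network(z)$A != 0), 0)
})

test_that("the worked-example subgraph yields the published path set", {
  net <- table2_network()
  rep <- enumerate_paths(net, "P38", "GSKa/b")
  expect_equal(length(rep$paths), 4)
  expect_setequal(rep$lengths, c(1, 2, 3, 6))
  pm <- path_metrics(rep)
  expect_equal(pm$count, 4)
  expect_equal(pm$mpl, 1)
  expect_equal(pm$apl, 3)
  # per-edge signs along the 3-edge path: P38 -| ERM -| AKT -> GSK
  i3 <- which(rep$lengths == 3)
  expect_equal(rep$paths[[i3]], c("P38", "ERM", "AKT", "GSKa/b"))
  expect_equal(unname(rep$signs[[i3]]), c(-1, -1, 1))
  # lexicographic ordering of the emitted node sequences
  keys <- vapply(rep$paths, paste, character(1), collapse = ">")
  expect_equal(keys, sort(keys))
})

test_that("path enumeration contracts and edge cases", {
  net <- table2_network()
  expect_error(enumerate_paths(net, "P38", "P38"), "differ")
  expect_error(enumerate_paths(net, "XXX", "AKT"), "Unknown")
  # GSKa/b has no outgoing edges
  none <- enumerate_paths(net, "GSKa/b", "P38")
  expect_equal(length(none$paths), 0)
  pm <- path_metrics(none)
  expect_equal(pm$count, 0)
  expect_true(is.na(pm$mpl) && is.na(pm$apl))
  one <- enumerate_paths(net, "ST1A/B", "PKCD")
  expect_equal(path_metrics(one)$mpl, path_metrics(one)$apl)
})

test_that("DFS agrees with brute force and igraph on random digraphs", {
  withr::local_seed(60)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    net <- random_signed_digraph(n, density = 0.35)
    st <- sample(net$nodes, 2)
    rep <- enumerate_paths(net, st[1], st[2])
    expect_identical(path_key(rep$paths),
                     path_key(brute_force_paths(net, st[1], st[2])))
  }
  skip_if_not_installed("igraph")
  net <- random_signed_digraph(7, density = 0.4)
  g <- igraph::graph_from_adjacency_matrix(abs(net$A), mode = "directed")
  rep <- enumerate_paths(net, "A", "B")
  ig <- igraph::all_simple_paths(g, "A", "B", mode = "out")
  expect_identical(path_key(rep$paths),
                   path_key(lapply(ig, function(p) names(p))))
})

test_that("variant-node merging averages ratios and drops sign conflicts", {
  prot <- c("GSKA", "GSKB", "AKT", "P38")
  B <- matrix(0, 4, 4, dimnames = list(prot, prot))
  sigma <- matrix(1, 4, 4, dimnames = dimnames(B))
  # AKT -> GSKA at ratio 3.0, AKT -> GSKB at 2.4: mean 2.7 survives 2.58
  B["GSKA", "AKT"] <- 3.0
  B["GSKB", "AKT"] <- 2.4
  # P38 edges agree into both variants
  B["GSKA", "P38"] <- 2.9
  B["GSKB", "P38"] <- 2.8
  et <- significant_edges(B, sigma, level = 0.99)
  net <- assemble_network(et)
  merged <- merge_variant_nodes(net, list(GSK = c("GSKA", "GSKB")))
  expect_equal(merged$A["AKT", "GSK"], 1L)
  expect_equal(merged$confidence["AKT", "GSK"], 2.7)
  expect_equal(merged$A["P38", "GSK"], 1L)

  # identical members reproduce the member edges
  B2 <- B; B2["GSKB", "AKT"] <- 3.0
  net2 <- assemble_network(significant_edges(B2, sigma, 0.99))
  m2 <- merge_variant_nodes(net2, list(GSK = c("GSKA", "GSKB")))
  expect_equal(m2$A["AKT", "GSK"], 1L)
  expect_equal(m2$confidence["AKT", "GSK"], 3.0)

  # opposite significant signs towards the same counterpart: edge dropped
  B3 <- B; B3["GSKB", "AKT"] <- -3.0
  net3 <- assemble_network(significant_edges(B3, sigma, 0.99))
  expect_warning(m3 <- merge_variant_nodes(net3, list(GSK = c("GSKA", "GSKB"))),
                 "conflict")
  expect_equal(m3$A["AKT", "GSK"], 0L)
  # non-conflicting P38 edge survives the merge
  expect_equal(m3$A["P38", "GSK"], 1L)

  expect_error(merge_variant_nodes(net, list(a = c("GSKA"), b = c("GSKA"))),
               "disjoint")
})

test_that("global metrics: complete digraph, chain, empty graph", {
  full <- network_from_edges(
    expand.grid(source = c("a", "b", "c"), target = c("a", "b", "c"),
                stringsAsFactors = FALSE) |>
      dplyr::filter(source != target) |>
      dplyr::mutate(sign = 1)
  )
  expect_equal(global_metrics(full)$avg_shortest_path, 1)

  chain <- network_from_edges(
    tibble::tibble(source = c("a", "b"), target = c("b", "c"), sign = 1)
  )
  gm <- global_metrics(chain)
  expect_equal(gm$avg_shortest_path, 4 / 3) # distances 1, 2, 1
  expect_equal(gm$avg_degree, 4 / 3)        # 4 endpoints over 3 nodes

  empty <- network_from_edges(
    tibble::tibble(source = character(0), target = character(0),
                   sign = integer(0)),
    nodes = c("a", "b")
  )
  expect_true(is.na(global_metrics(empty)$avg_shortest_path))
})

test_that("network exports round-trip and style edges by sign", {
  net <- table2_network()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- read_network_tsv(tsv, nodes = net$nodes)
  expect_identical(back$A, net$A)

  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  lines <- readLines(dot)
  expect_true(any(grepl("\"AKT\" -> \"GSKa/b\" \\[arrowhead=normal", lines)))
  expect_true(any(grepl("\"P38\" -> \"ERM\" \\[arrowhead=tee", lines)))

  skip_if_not_installed("igraph")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 7)
  expect_equal(igraph::gsize(g), 9)
})
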