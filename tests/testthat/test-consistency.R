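# A hand-built screen around a GSK-like node with two positive incoming
# edges (AKT ->, P38 ->), engineered so each experiment lands in a known
# class.
consistency_fixture <- function() {
  prot <- c("AKT", "P38", "GSK")
  net <- network_from_edges(
    tibble::tibble(source = c("AKT", "P38"), target = "GSK", sign = 1L),
    nodes = prot
  )
  # log2 values at (t_in = 1) for AKT, P38 and at (t_out = 3) for GSK
  design <- tibble::tribble(
    ~experiment_id, ~ligands,    ~akt, ~p38, ~gsk,
    "E0001",        "GMF+I1B",    0.5,  0.8, -0.6, # both + but target -: none
    "E0002",        "LPS",        0.7,  0.4,  0.9, # both consistent
    "E0003",        "PGE",        0.6, -0.5,  0.8, # AKT only (path1)
    "E0004",        "UDP",       -0.4,  0.6,  0.7, # P38 only (path2)
    "E0005",        "ISO",       -0.3, -0.2,  0.5, # neither: none
    "E0006",        "MCF+S1P",    0.2,  0.3,  0.4  # both consistent
  )
  rows <- purrr::pmap_dfr(design, function(experiment_id, ligands, akt, p38,
                                           gsk) {
    tibble::tibble(
      experiment_id = experiment_id, ligands = ligands, replicate = 1L,
      time_min = rep(c(0, 1, 3), each = 3),
      protein = rep(prot, 3),
      fold_change = 2^c(0, 0, 0,
                        akt, p38, 0.1,
                        0.2, 0.3, gsk)
    )
  })
  list(net = net, screen = as_screen(rows))
}

test_that("the four-way classification applies the sign rule", {
  fx <- consistency_fixture()
  rep <- classify_experiments(fx$net, "GSK", fx$screen, t_in = 1, t_out = 3)
  expect_equal(rep$predecessors, c("AKT", "P38"))
  cls <- setNames(as.character(rep$cases$class), rep$cases$experiment_id)
  expect_equal(unname(cls[c("E0001", "E0002", "E0003", "E0004", "E0005",
                            "E0006")]),
               c("none", "both", "path1", "path2", "none", "both"))
  # classes partition the classified cases
  expect_equal(sum(rep$counts), 6)
  expect_equal(unname(rep$counts[c("none", "path1", "path2", "both")]),
               c(2L, 1L, 1L, 2L), ignore_attr = TRUE)
})

test_that("classification depends only on signs", {
  fx <- consistency_fixture()
  rep1 <- classify_experiments(fx$net, "GSK", fx$screen)
  # raising fold-changes to a positive power preserves every log2 sign
  scaled <- fx$screen
  scaled$fold_change <- scaled$fold_change^3
  rep2 <- classify_experiments(fx$net, "GSK", as_screen(scaled))
  expect_equal(as.character(rep1$cases$class), as.character(rep2$cases$class))
})

test_that("a zero log2 value is consistent with neither sign", {
  fx <- consistency_fixture()
  flat <- fx$screen
  flat$fold_change[flat$protein == "AKT" & flat$time_min == 1 &
                     flat$experiment_id == "E0002"] <- 1 # log2 = 0
  rep <- classify_experiments(fx$net, "GSK", as_screen(flat))
  expect_equal(as.character(rep$cases$class[rep$cases$experiment_id == "E0002"]),
               "path2")
})

test_that("in-degree other than two is rejected with guidance", {
  fx <- consistency_fixture()
  net1 <- network_from_edges(
    tibble::tibble(source = "AKT", target = "GSK", sign = 1L),
    nodes = c("AKT", "P38", "GSK")
  )
  expect_error(classify_experiments(net1, "GSK", fx$screen), "in-degree 1")
  expect_error(classify_experiments(fx$net, "XXX", fx$screen), "Unknown")
})

test_that("ligand distribution double-counts dual-ligand experiments", {
  fx <- consistency_fixture()
  rep <- classify_experiments(fx$net, "GSK", fx$screen)
  ld <- ligand_distribution(rep)
  # E0001 is GMF+I1B in class none: both ligands incremented
  expect_equal(ld$n[ld$ligand == "GMF" & ld$class == "none"], 1)
  expect_equal(ld$n[ld$ligand == "I1B" & ld$class == "none"], 1)
  # single-ligand experiment increments exactly one ligand
  expect_equal(sum(ld$n[ld$ligand == "LPS"]), 1)
  # total mass: 4 single + 2 dual experiments -> 4 + 2*2
  expect_equal(sum(ld$n), 8)
  # summing classes recovers each ligand's double-counted total
  per_lig <- ld |> dplyr::group_by(ligand) |> dplyr::summarise(n = sum(n))
  expect_equal(sum(per_lig$n[per_lig$ligand %in% c("MCF", "S1P")]), 2)
})

test_that("consistency matrix exposes the class panel values", {
  fx <- consistency_fixture()
  rep <- classify_experiments(fx$net, "GSK", fx$screen)
  m <- consistency_matrix(rep, "both")
  expect_equal(sort(m$experiment_id), c("E0002", "E0006"))
  expect_equal(names(m)[4:6], c("AKT", "P38", "GSK"))
  expect_equal(m$GSK[m$experiment_id == "E0002"], 0.9)
})
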