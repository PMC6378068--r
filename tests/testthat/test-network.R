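tiny_ct <- function() {
  edges <- data.frame(
    mol_id = c("c1", "c1", "c2", "c3", "c3", "c3"),
    gene_symbol = c("G1", "G2", "G1", "G1", "G2", "G3"),
    stringsAsFactors = FALSE)
  build_ct_network(c("c1", "c2", "c3"), c("G1", "G2", "G3"), edges)
}

test_that("compound-target networks exclude non-qualifying entities", {
  edges <- data.frame(mol_id = c("c1", "c2", "c9"),
                      gene_symbol = c("G1", "ZZ", "G1"),
                      stringsAsFactors = FALSE)
  net <- build_ct_network(c("c1", "c2"), c("G1"), edges)
  expect_identical(net$side_a, "c1")
  expect_identical(net$side_b, "G1")
  expect_identical(nrow(net$edges), 1L)
  # a compound with no qualifying edge is absent: no isolated nodes
  expect_false("c2" %in% net$side_a)
})

test_that("degree statistics conserve the degree sum on both sides", {
  net <- tiny_ct()
  rep <- degree_statistics(net)
  expect_identical(rep$n_edges, 6L)
  expect_identical(rep$n_nodes, 6L)
  degs <- setNames(rep$degrees$degree, rep$degrees$node)
  expect_identical(unname(degs[c("c1", "c2", "c3")]), c(2L, 1L, 3L))
  expect_identical(sum(degs[net$side_a]), rep$n_edges)
  expect_identical(sum(degs[net$side_b]), rep$n_edges)
  expect_equal(rep$mean_degree_side_a, 2)
  expect_equal(rep$mean_degree_side_b, 2)
  # hub ranking: degree descending, ties by node id ascending
  expect_identical(rep$hubs$node[1:2], c("G1", "c3"))
  expect_identical(rep$hubs$degree[1:2], c(3L, 3L))
})

test_that("a star graph yields the expected degrees", {
  edges <- data.frame(mol_id = "hub", gene_symbol = sprintf("G%02d", 1:7))
  net <- build_ct_network("hub", edges$gene_symbol, edges)
  rep <- degree_statistics(net)
  degs <- setNames(rep$degrees$degree, rep$degrees$node)
  expect_identical(unname(degs["hub"]), 7L)
  expect_true(all(degs[net$side_b] == 1L))
})

test_that("degree sums are conserved on random bipartite networks", {
  for (seed in 1:8) {
    set.seed(seed)
    edges <- unique(data.frame(
      mol_id = sample(sprintf("c%02d", 1:15), 40, replace = TRUE),
      gene_symbol = sample(sprintf("G%02d", 1:25), 40, replace = TRUE),
      stringsAsFactors = FALSE))
    net <- build_ct_network(unique(edges$mol_id),
                            unique(edges$gene_symbol), edges)
    rep <- degree_statistics(net)
    expect_identical(sum(rep$degrees$degree[rep$degrees$side == "a"]),
                     rep$n_edges)
    expect_identical(sum(rep$degrees$degree[rep$degrees$side == "b"]),
                     rep$n_edges)
    expect_identical(rep$n_nodes,
                     length(unique(edges$mol_id)) +
                       length(unique(edges$gene_symbol)))
  }
})

test_that("target-pathway networks link overlap genes to retained pathways only", {
  col <- gene_set_collection(list(pwA = c("G1", "G2", "G9"),
                                  pwB = c("G2", "G3"),
                                  pwC = c("G7")))
  net <- build_tp_network(c("G1", "G2", "G3"), c("pwA", "pwB"), col)
  expect_setequal(net$side_a, c("G1", "G2", "G3"))
  expect_setequal(net$side_b, c("pwA", "pwB"))
  rep <- degree_statistics(net)
  degs <- setNames(rep$degrees$degree, rep$degrees$node)
  # a gene in two retained pathways has degree 2
  expect_identical(unname(degs["G2"]), 2L)
  empty <- build_tp_network(c("G1"), character(0), col)
  expect_identical(degree_statistics(empty)$n_edges, 0L)
})

test_that("network export is deterministic and GraphML round-trips", {
  net <- tiny_ct()
  f1 <- tempfile(fileext = ".graphml")
  f2 <- tempfile(fileext = ".graphml")
  export_network(net, f1, "graphml")
  export_network(net, f2, "graphml")
  expect_identical(readLines(f1), readLines(f2))
  back <- import_network_graphml(f1)
  expect_identical(back$edges, net$edges)
  expect_identical(back$side_a, net$side_a)
  expect_identical(back$side_b, net$side_b)

  sif <- tempfile(fileext = ".sif")
  one_edge <- build_ct_network("c1", "G1",
                               data.frame(mol_id = "c1",
                                          gene_symbol = "G1"))
  export_network(one_edge, sif, "sif")
  expect_identical(readLines(sif), "c1 interacts G1")
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  expect_identical(nrow(read.delim(tsv)), 6L)
  expect_error(export_network(net, tempfile(), "dot"), "arg")
})

test_that("within-side edges are rejected", {
  expect_error(bipartite_network(data.frame(from = c("x", "y"),
                                            to = c("y", "z")),
                                 "compound", "target"),
               "both sides")
})
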