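test_that("inconsistent fixture specs are rejected with the violated identities", {
  expect_error(fixture_spec(hub_degree = 500L), "hub degree")
  expect_error(fixture_spec(ct_edges = 50L), "degree plan")
  expect_error(fixture_spec(top_pathway_overlap = 120L), "top pathway")
  expect_error(fixture_spec(screen_pass = 10L), "screen passes")
})

test_that("fixture generation is byte-deterministic for a given seed", {
  d1 <- file.path(tempdir(), "fx_det_a")
  d2 <- file.path(tempdir(), "fx_det_b")
  s1 <- generate_paper_shape_fixture(fixture_spec(seed = 5L), d1)
  s2 <- generate_paper_shape_fixture(fixture_spec(seed = 5L), d2)
  for (f in unlist(s1$files)) {
    g <- file.path(d2, basename(f))
    expect_identical(readLines(f), readLines(g))
  }
  s3 <- generate_paper_shape_fixture(fixture_spec(seed = 6L),
                                     file.path(tempdir(), "fx_det_c"))
  expect_false(identical(readLines(s1$files$edges),
                         readLines(s3$files$edges)))
})

test_that("the fixture reproduces every pinned count through the real pipeline stages", {
  scn <- cached_fixture()
  truth <- scn$truth
  herb_lists <- lapply(names(scn$files$compounds), function(h) {
    read_compound_table(scn$files$compounds[[h]], h)
  })
  merged <- merge_herb_lists(herb_lists)
  expect_identical(nrow(merged), truth$n_unique)
  expect_identical(attr(merged, "n_duplicates"), truth$n_duplicates)

  config <- read_pipeline_config(scn$files$config)
  scr <- screen_compounds(merged, screening_criteria(), config$whitelist)
  expect_length(scr$passed, truth$n_passed)
  expect_identical(sort(scr$rescued), truth$whitelist)
  active <- active_compounds(scr)
  expect_length(active, truth$n_active)

  edges <- filter_predicted_edges(read_edge_list(scn$files$edges),
                                  config$confidence_min)
  tmap <- build_target_map(active, edges)
  expect_length(tmap$target_universe, truth$target_universe)

  disease <- read_gene_list(scn$files$disease)
  expect_length(disease$genes, truth$disease_genes)
  overlap <- intersect_disease_genes(tmap, disease)
  expect_length(overlap$overlap_genes, truth$overlap)
  pruned <- prune_compounds(overlap, active)
  expect_identical(pruned$n_final, truth$n_final)
  expect_identical(sort(pruned$dropped_compounds), truth$dropped_compounds)

  ct <- build_ct_network(pruned$final_compounds, overlap$overlap_genes,
                         overlap$overlap_edges)
  deg <- degree_statistics(ct)
  expect_identical(deg$n_nodes, truth$ct_nodes)
  expect_identical(deg$n_edges, truth$ct_edges)
  degs <- setNames(deg$degrees$degree, deg$degrees$node)
  expect_identical(unname(degs[truth$hub_id]), truth$hub_degree)
  expect_identical(deg$hubs$node[1], truth$hub_id)

  pw <- read_gmt(scn$files$pathway_gmt, "KEGG")
  pres <- enrich(overlap$overlap_genes, pw, fdr_max = config$fdr_max)
  expect_identical(sum(pres$retained), truth$pathways_retained)
  tp <- build_tp_network(overlap$overlap_genes, pres, pw)
  expect_length(tp$side_a, truth$tp_targets)
  expect_length(tp$side_b, truth$pathways_retained)
  tp_degs <- degree_statistics(tp)$degrees
  expect_identical(tp_degs$degree[tp_degs$node == truth$top_pathway],
                   truth$top_pathway_degree)

  go <- read_gmt(scn$files$go_gmt, "GO_BP")
  gres <- enrich(overlap$overlap_genes, go, fdr_max = config$fdr_max)
  expect_identical(sum(gres$retained), truth$go_retained)
})

test_that("enrichment scenarios are seed-reproducible with exact ground truth", {
  a <- generate_enrichment_scenario(seed = 21L)
  b <- generate_enrichment_scenario(seed = 21L)
  expect_identical(a$query, b$query)
  expect_identical(a$collection$sets, b$collection$sets)
  # planted sets carry exactly fold x expected query members
  for (id in a$truth$planted) {
    expect_identical(length(intersect(a$collection$sets[[id]], a$query)),
                     as.integer(a$truth$planted_k))
  }
  c_ <- generate_enrichment_scenario(seed = 22L)
  expect_false(identical(a$query, c_$query))
  expect_error(generate_enrichment_scenario(set_size = 10L,
                                            fold_enrichment = 600),
               "infeasible fold")
})

test_that("null scenarios carry no planted structure", {
  scn <- generate_enrichment_scenario(fold_enrichment = 1, seed = 3L)
  expect_length(scn$truth$planted, 0L)
  expect_length(scn$query, scn$params$query_size)
  expect_true(all(scn$query %in% scn$universe))
})

test_that("reference descriptor tables are reproducible and non-negative", {
  a <- generate_reference_descriptor_set(50, 5, seed = 2L)
  b <- generate_reference_descriptor_set(50, 5, seed = 2L)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_identical(dim(a), c(50L, 5L))
  profile <- compute_reference_profile(a)
  # the reference mean is maximally drug-like against its own profile
  expect_equal(compute_dl(profile$b_vector, profile), 1)
})
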