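test_that("compound tables parse ADME columns, descriptors and row order", {
  path <- write_tmp_tsv(c(
    "mol_id\tname\tob\tdl\tcaco2\tdesc_logp\tdesc_mw",
    "MOL000006\tLuteolin\t36.16\t0.25\t0.19\t2.5\t286.2",
    "MOL000409\tAstragaloside IV\t17.74\t0.15\t(2.22)\t0.2\t784.9"))
  tab <- read_compound_table(path, "PHP")
  expect_s3_class(tab, "herb_compound_list")
  expect_identical(tab$mol_id, c("MOL000006", "MOL000409"))
  expect_equal(tab$ob, c(36.16, 17.74))
  expect_equal(tab$dl, c(0.25, 0.15))
  # parenthesized negatives are database shorthand for minus
  expect_equal(tab$caco2, c(0.19, -2.22))
  expect_equal(tab$desc_mw, c(286.2, 784.9))
  expect_identical(attr(tab, "herb_code"), "PHP")
})

test_that("compound table round trip reproduces the parsed records", {
  tab <- wpx_representative_compounds()
  out <- tempfile(fileext = ".tsv")
  write_compound_table(tab, out)
  again <- read_compound_table(out, "WPX")
  class(again) <- "data.frame"
  attr(again, "herb_code") <- NULL
  expect_equal(again, tab)
})

test_that("compound table readers reject malformed input", {
  no_col <- write_tmp_tsv(c("mol_id\tname\tob\tdl",
                            "MOL1\tx\t30\t0.2"))
  expect_error(read_compound_table(no_col, "X"), "caco2")
  bad_num <- write_tmp_tsv(c("mol_id\tname\tob\tdl\tcaco2",
                             "MOL1\tx\tthirty\t0.2\t0"))
  expect_error(read_compound_table(bad_num, "X"), "row 1")
  dup <- write_tmp_tsv(c("mol_id\tname\tob\tdl\tcaco2",
                         "MOL1\tx\t30\t0.2\t0",
                         "MOL1\ty\t31\t0.3\t0"))
  expect_error(read_compound_table(dup, "X"), "duplicate")
  empty <- write_tmp_tsv("mol_id\tname\tob\tdl\tcaco2")
  expect_identical(nrow(read_compound_table(empty, "X")), 0L)
})

test_that("edge lists normalize symbols and collapse duplicates by max confidence", {
  path <- write_tmp_tsv(c(
    "mol_id\tgene_symbol\tsource\tconfidence",
    "MOL000098\tptgs2\tcurated\t",
    "MOL000098\tCASP3\tpredicted\t0.5",
    "MOL000098\tcasp3 \tpredicted\t0.7"))
  edges <- read_edge_list(path)
  expect_identical(edges$gene_symbol, c("PTGS2", "CASP3"))
  expect_equal(edges$confidence[edges$gene_symbol == "CASP3"], 0.7)

  no_conf <- write_tmp_tsv(c("mol_id\tgene_symbol\tsource",
                             "MOL1\tTP53\tpredicted"))
  expect_error(read_edge_list(no_conf), "without confidence")
  out_of_range <- write_tmp_tsv(c("mol_id\tgene_symbol\tsource\tconfidence",
                                  "MOL1\tTP53\tpredicted\t1.2"))
  expect_error(read_edge_list(out_of_range), "outside")
})

test_that("edge list round trip preserves edges", {
  path <- write_tmp_tsv(c("mol_id\tgene_symbol\tsource\tconfidence",
                          "MOL1\tTP53\tcurated\t",
                          "MOL2\tJUN\tpredicted\t0.55"))
  edges <- read_edge_list(path)
  out <- tempfile(fileext = ".tsv")
  write_edge_list(edges, out)
  expect_equal(read_edge_list(out), edges)
})

test_that("GMT files parse one set per line with set semantics", {
  path <- write_tmp_tsv(c("hsa05200\tPathways in cancer\tTP53\tAKT1",
                          "hsa04151\tPI3K-Akt\ttp53\tTP53\tCCND1"),
                        ext = ".gmt")
  col <- read_gmt(path, namespace = "KEGG")
  expect_identical(names(col$sets), c("hsa05200", "hsa04151"))
  expect_setequal(col$sets$hsa05200, c("TP53", "AKT1"))
  # duplicated gene on one line stored once, uppercased
  expect_setequal(col$sets$hsa04151, c("TP53", "CCND1"))

  short <- write_tmp_tsv(c("hsa05200\tPathways in cancer\tTP53",
                           "broken\tonly-two-fields"), ext = ".gmt")
  expect_error(read_gmt(short), "line 2")
  empty <- write_tmp_tsv(character(0), ext = ".gmt")
  expect_length(read_gmt(empty)$sets, 0L)

  out <- tempfile(fileext = ".gmt")
  write_gmt(col, out)
  expect_equal(read_gmt(out, "KEGG"), col)
})

test_that("gene lists are normalized and tolerate comments and blanks", {
  path <- write_tmp_tsv(c("# disease genes", "tp53", "", " CASP3 ", "tp53"))
  gl <- read_gene_list(path, label = "GPL")
  expect_identical(gl$genes, c("TP53", "CASP3"))
  expect_identical(gl$disease_label, "GPL")
  only_comments <- write_tmp_tsv(c("# nothing", "# here"))
  expect_warning(empty <- read_gene_list(only_comments), "empty")
  expect_length(empty$genes, 0L)
})

test_that("pipeline config round-trips through YAML and hashes semantically", {
  cfg <- pipeline_config(whitelist = c(MOL000409 = "major constituent"),
                         modules = list(hsa05200 = "apoptosis"), seed = 3L)
  path <- tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, path)
  back <- read_pipeline_config(path)
  expect_equal(back$ob_min, 30)
  expect_equal(back$fdr_max, 0.01)
  expect_identical(names(back$whitelist), "MOL000409")
  expect_identical(back$seed, 3L)
  expect_identical(config_hash(back), config_hash(cfg))
  bumped <- cfg
  bumped$dl_min <- 0.2
  expect_false(identical(config_hash(bumped), config_hash(cfg)))
  expect_error(pipeline_config(fdr_max = 0), "fdr_max")
  expect_error(pipeline_config(ob_min = Inf), "finite")
})
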