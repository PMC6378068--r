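# End-to-end orchestration: merge -> screen -> map targets -> intersect/
# prune -> enrich (GO + pathways) -> networks -> integrated pathway,
# writing every intermediate artifact plus a machine-readable run report
# whose counts satisfy the pipeline identities by construction.

#' Run the full systems-pharmacology pipeline
#'
#' Executes every stage on the given input files and writes the
#' intermediate tables (TSV), networks (GraphML) and a JSON run report
#' with fixed key order into \code{out_dir}. The run is fully
#' deterministic given the config and inputs; any stage error aborts
#' with the stage name, leaving earlier artifacts plus a \code{FAILED}
#' marker file in place.
#'
#' @param config a \code{\link{pipeline_config}} or path to a YAML
#'   config file.
#' @param inputs list with elements \code{compounds} (named character
#'   vector herb_code -> TSV path), \code{edges} (TSV path),
#'   \code{disease} (gene list path), and optional \code{go_gmt} and
#'   \code{pathway_gmt} (GMT paths).
#' @param out_dir output directory for artifacts (created if needed).
#' @return the run report, an object of class \code{run_report} (a named
#'   list of per-stage counts, the config hash, seed and timestamps),
#'   invisibly also written to \code{report.json}.
#' @export
run_pipeline <- function(config, inputs, out_dir = tempfile("netpharm_run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  stage <- "setup"
  fail_marker <- file.path(out_dir, "FAILED")
  on.exit(if (!file.exists(file.path(out_dir, "report.json"))) {
    writeLines(sprintf("pipeline failed at stage: %s", stage), fail_marker)
  })

  stage <- "merge"
  herb_lists <- lapply(names(inputs$compounds), function(h) {
    read_compound_table(inputs$compounds[[h]], herb_code = h)
  })
  merged <- merge_herb_lists(herb_lists)
  write_compound_table(merged, file.path(out_dir, "merged_compounds.tsv"))

  stage <- "screen"
  criteria <- screening_criteria(config$ob_min, config$dl_min,
                                 config$caco2_min)
  scr <- screen_compounds(merged, criteria, whitelist = config$whitelist)
  write.table(scr$table, file.path(out_dir, "screening.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")
  active <- active_compounds(scr)

  stage <- "map_targets"
  edges <- read_edge_list(inputs$edges)
  edges <- filter_predicted_edges(edges, config$confidence_min)
  tmap <- build_target_map(active, edges)

  stage <- "intersect"
  disease <- read_gene_list(inputs$disease, label = "disease")
  overlap <- intersect_disease_genes(tmap, disease)
  pruned <- prune_compounds(overlap, active)
  write_gene_list(overlap$overlap_genes,
                  file.path(out_dir, "overlap_genes.txt"))
  write.table(data.frame(mol_id = c(pruned$final_compounds,
                                    pruned$dropped_compounds),
                         status = rep(c("retained", "dropped"),
                                      c(pruned$n_final, pruned$n_dropped))),
              file.path(out_dir, "final_compounds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")

  stage <- "enrich"
  universe_arg <- if (identical(config$universe, "collection")) NULL
                  else config$universe
  go_res <- pathway_res <- NULL
  if (!is.null(inputs$go_gmt)) {
    go <- read_gmt(inputs$go_gmt, namespace = "GO_BP")
    go_res <- enrich(overlap$overlap_genes, go, universe = universe_arg,
                     fdr_max = config$fdr_max)
    write.table(go_res, file.path(out_dir, "enrichment_go.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  }
  if (!is.null(inputs$pathway_gmt)) {
    pw <- read_gmt(inputs$pathway_gmt, namespace = "KEGG")
    pathway_res <- enrich(overlap$overlap_genes, pw,
                          universe = universe_arg,
                          fdr_max = config$fdr_max)
    write.table(pathway_res, file.path(out_dir, "enrichment_pathways.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  }

  stage <- "networks"
  cname <- setNames(merged$name, merged$mol_id)
  ct <- build_ct_network(pruned$final_compounds, overlap$overlap_genes,
                         overlap$overlap_edges, compound_names = cname)
  ct_deg <- degree_statistics(ct)
  if (nrow(ct$edges) > 0L) {
    export_network(ct, file.path(out_dir, "ct_network.graphml"), "graphml")
    write.table(ct_deg$degrees, file.path(out_dir, "ct_degrees.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  }
  tp <- NULL
  tp_deg <- NULL
  if (!is.null(pathway_res)) {
    tp <- build_tp_network(overlap$overlap_genes, pathway_res, pw)
    tp_deg <- degree_statistics(tp)
    if (nrow(tp$edges) > 0L) {
      export_network(tp, file.path(out_dir, "tp_network.graphml"),
                     "graphml")
      write.table(tp_deg$degrees, file.path(out_dir, "tp_degrees.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    }
  }

  stage <- "integrate"
  integrated <- NULL
  if (!is.null(tp) && !is.null(config$modules) &&
      length(config$modules) > 0L && nrow(retained_sets(pathway_res)) > 0L) {
    mc <- module_config(config$modules)
    skeleton <- assign_modules(pathway_res, mc)
    skeleton$pathways <- skeleton$pathways[
      skeleton$pathways$set_id %in% tp$side_b, , drop = FALSE]
    integrated <- build_integrated_pathway(tp, skeleton)
    write_integrated_annotation(integrated,
                                file.path(out_dir,
                                          "integrated_targets.tsv"))
  }

  stage <- "report"
  report <- structure(list(
    unique_compounds = nrow(merged),
    duplicate_memberships = attr(merged, "n_duplicates"),
    passed = length(scr$passed),
    rescued = length(scr$rescued),
    rejected = length(scr$rejected),
    active = length(active),
    screen_yield_pct = round(100 * length(scr$passed) / nrow(merged), 2),
    target_universe = length(tmap$target_universe),
    disease_genes = length(disease$genes),
    overlap_genes = length(overlap$overlap_genes),
    final_compounds = pruned$n_final,
    dropped_compounds = pruned$n_dropped,
    go_tested = if (is.null(go_res)) NA_integer_ else nrow(go_res),
    go_retained = if (is.null(go_res)) NA_integer_
                  else sum(go_res$retained),
    pathways_tested = if (is.null(pathway_res)) NA_integer_
                      else nrow(pathway_res),
    pathways_retained = if (is.null(pathway_res)) NA_integer_
                        else sum(pathway_res$retained),
    ct_nodes = ct_deg$n_nodes,
    ct_edges = ct_deg$n_edges,
    mean_edges_per_compound = ct_deg$mean_degree_side_a,
    mean_degree_per_target = ct_deg$mean_degree_side_b,
    tp_targets = if (is.null(tp_deg)) NA_integer_
                 else length(tp$side_a),
    tp_pathways = if (is.null(tp_deg)) NA_integer_
                  else length(tp$side_b),
    integrated_pathways = if (is.null(integrated)) NA_integer_
                          else nrow(integrated$pathways),
    integrated_targets = if (is.null(integrated)) NA_integer_
                         else nrow(integrated$targets),
    config_hash = config_hash(config),
    seed = config$seed,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_report")
  validate_run_report(report)
  jsonlite::write_json(unclass(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  if (file.exists(fail_marker)) unlink(fail_marker)
  invisible(report)
}

# internal consistency of the per-stage counts
validate_run_report <- function(report) {
  stopifnot(
    report$active == report$passed + report$rescued,
    report$passed + report$rescued + report$rejected ==
      report$unique_compounds,
    report$final_compounds + report$dropped_compounds == report$active,
    report$overlap_genes <= report$target_universe,
    report$overlap_genes <= report$disease_genes,
    report$ct_nodes <= report$final_compounds + report$overlap_genes
  )
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("systems-pharmacology run report\n")
  cat(sprintf("  compounds: %d unique -> %d passed + %d rescued = %d active -> %d final\n",
              x$unique_compounds, x$passed, x$rescued, x$active,
              x$final_compounds))
  cat(sprintf("  targets:   %d in universe, %d disease genes, %d overlap\n",
              x$target_universe, x$disease_genes, x$overlap_genes))
  cat(sprintf("  enrichment: %s GO terms, %s pathways retained\n",
              x$go_retained, x$pathways_retained))
  cat(sprintf("  C-T network: %d nodes / %d edges (means %.2f per compound, %.2f per target)\n",
              x$ct_nodes, x$ct_edges, x$mean_edges_per_compound,
              x$mean_degree_per_target))
  if (!is.na(x$tp_targets)) {
    cat(sprintf("  T-P network: %d targets x %d pathways\n",
                x$tp_targets, x$tp_pathways))
  }
  invisible(x)
}
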