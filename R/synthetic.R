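# Synthetic-data generators. Two kinds of output:
# (a) a deterministic formula-shaped fixture whose files, run through the
#     real pipeline stages, reproduce the pinned stage counts of the
#     six-herb study design (counting patterns, not rejection sampling:
#     every pinned count is realized by explicit partitioning, and only
#     non-pinned quantities such as the ADME spread are sampled);
# (b) stochastic planted-enrichment scenarios with exact ground truth for
#     statistical calibration and recovery tests.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of the formula-shaped fixture
#'
#' Pins every stage count of the six-herb study design: per-herb compound
#' counts 87/25/55/202/81/37 with 55 cross-herb duplicates (432 unique),
#' 88 screen passes (20.37\%), a 5-compound whitelist (93 active), a
#' 306-gene predicted-target universe, a 1261-gene disease list with a
#' 146-gene overlap, 11 target-less candidates (82 final), a 677-edge
#' compound-target network with one degree-104 hub, and a pathway plan of
#' 21 retained sets covering 97 mapped targets with a top set of
#' in-overlap size 57 (plus 26 retained GO terms).
#'
#' @param seed integer seed for the (non-pinned) sampled quantities.
#' @param per_herb named integer vector of per-herb compound counts.
#' @param duplicates number of cross-herb duplicate memberships.
#' @param screen_pass number of compounds passing the three-criterion
#'   screen.
#' @param targetless number of active compounds left without
#'   disease-relevant targets.
#' @param target_universe number of genes targeted by active compounds.
#' @param disease_genes size of the disease gene list.
#' @param overlap size of the target/disease intersection.
#' @param ct_edges compound-target edge count over the final compounds.
#' @param hub_degree degree of the hub compound (a quercetin analog).
#' @param pathways_retained number of pathway sets surviving FDR.
#' @param tp_targets number of overlap genes mapped to retained pathways.
#' @param top_pathway_overlap in-overlap size of the largest pathway.
#' @param go_retained number of GO terms surviving FDR.
#' @return a list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 0L,
                         per_herb = c(HMM = 87L, PHP = 25L, AMK = 55L,
                                      RMB = 202L, CZR = 81L, HDW = 37L),
                         duplicates = 55L, screen_pass = 88L,
                         targetless = 11L, target_universe = 306L,
                         disease_genes = 1261L, overlap = 146L,
                         ct_edges = 677L, hub_degree = 104L,
                         pathways_retained = 21L, tp_targets = 97L,
                         top_pathway_overlap = 57L, go_retained = 26L) {
  spec <- structure(list(seed = as.integer(seed), per_herb = per_herb,
                         duplicates = as.integer(duplicates),
                         screen_pass = as.integer(screen_pass),
                         targetless = as.integer(targetless),
                         target_universe = as.integer(target_universe),
                         disease_genes = as.integer(disease_genes),
                         overlap = as.integer(overlap),
                         ct_edges = as.integer(ct_edges),
                         hub_degree = as.integer(hub_degree),
                         pathways_retained = as.integer(pathways_retained),
                         tp_targets = as.integer(tp_targets),
                         top_pathway_overlap = as.integer(top_pathway_overlap),
                         go_retained = as.integer(go_retained)),
                    class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

# pinned degrees of the named analog compounds within the fixture's
# compound-target network; the hub entry tracks spec$hub_degree
fixture_pinned_degrees <- function(spec) {
  c(MOL000098 = spec$hub_degree, MOL000006 = 46L, MOL000422 = 37L,
    MOL000354 = 37L, MOL001689 = 20L, MOL000409 = 4L)
}

validate_fixture_spec <- function(spec) {
  core <- wpx_representative_compounds()
  scr <- screen_compounds(core, screening_criteria(),
                          whitelist = core$mol_id)
  n_core <- nrow(core)
  core_pass <- length(scr$passed)
  core_fail <- n_core - core_pass
  n_unique <- sum(spec$per_herb) - spec$duplicates
  n_active <- spec$screen_pass + core_fail
  n_final <- n_active - spec$targetless
  pinned <- fixture_pinned_degrees(spec)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_unique > n_core, "unique compound count must exceed the core table")
  chk(spec$duplicates >= sum(grepl(",", core$herbs)),
      "cross-herb duplicates cannot be fewer than in the core table")
  chk(spec$screen_pass >= core_pass + spec$targetless,
      "screen passes must cover the core passes plus target-less compounds")
  chk(spec$overlap <= spec$target_universe,
      "overlap cannot exceed the target universe")
  chk(spec$overlap <= spec$disease_genes,
      "overlap cannot exceed the disease gene list")
  chk(spec$hub_degree <= spec$overlap, "hub degree cannot exceed overlap")
  chk(all(pinned <= spec$overlap), "pinned degrees cannot exceed overlap")
  chk(spec$ct_edges >= sum(pinned) + (n_final - length(pinned)),
      "edge count too small for the degree plan")
  chk(spec$ct_edges <= n_final * spec$overlap,
      "edge count exceeds the bipartite capacity")
  chk(spec$tp_targets <= spec$overlap,
      "mapped targets cannot exceed overlap genes")
  chk(spec$top_pathway_overlap <= spec$tp_targets,
      "top pathway overlap cannot exceed the mapped targets")
  chk(spec$pathways_retained >= 1L, "need at least one retained pathway")
  if (length(problems) > 0L) {
    stop(paste0("inconsistent fixture spec:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(spec)
}

# deterministic herb assignment: duplicates take the two herbs with the
# largest remaining quota, singles the largest; ties broken by herb code
assign_fixture_herbs <- function(remaining, n_dup, n_single) {
  herbs <- names(remaining)
  pairs <- character(n_dup)
  for (i in seq_len(n_dup)) {
    ord <- order(-remaining, herbs)
    pick <- sort(herbs[ord[1:2]])
    pairs[i] <- paste(pick, collapse = ",")
    remaining[pick] <- remaining[pick] - 1L
  }
  singles <- character(n_single)
  for (i in seq_len(n_single)) {
    ord <- order(-remaining, herbs)
    singles[i] <- herbs[ord[1]]
    remaining[herbs[ord[1]]] <- remaining[herbs[ord[1]]] - 1L
  }
  if (!all(remaining == 0L)) {
    stop("herb quota not exhausted; per-herb counts are inconsistent",
         call. = FALSE)
  }
  c(pairs, singles)
}

# windows of length k over a cyclic index range, advancing a shared
# pointer so that consecutive windows tile the range
cyclic_window <- function(pointer, k, size) {
  idx <- ((pointer + seq_len(k) - 1L) %% size) + 1L
  list(idx = idx, pointer = (pointer + k) %% size)
}

fixture_gene_pools <- function(spec) {
  real <- c("PTGS2", "CASP3", "JUN", "AKT1", "TP53", "TNF", "IL6", "IL1B",
            "VEGFA", "EGFR", "MAPK1", "MAPK8", "CCND1", "BCL2", "BAX",
            "FOS", "MYC", "NFKB1", "STAT3", "HIF1A")
  n_real <- min(length(real), spec$overlap)
  overlap <- c(real[seq_len(n_real)],
               sprintf("GPLT%04d", seq_len(spec$overlap - n_real)))
  list(overlap = overlap,
       nonoverlap = sprintf("NTGT%04d",
                            seq_len(spec$target_universe - spec$overlap)),
       disease_only = sprintf("DISG%04d",
                              seq_len(spec$disease_genes - spec$overlap)))
}

# named pathway/GO plans: (id, name, in-overlap size); sizes beyond the
# named entries follow a deterministic 7..17 cycle
fixture_set_plan <- function(n_sets, top_k, named_ids, named_names, named_ks) {
  n_named <- min(length(named_ids), n_sets)
  ks <- named_ks[seq_len(n_named)]
  ids <- named_ids[seq_len(n_named)]
  nms <- named_names[seq_len(n_named)]
  extra <- n_sets - n_named
  if (extra > 0L) {
    i <- seq_len(extra)
    ids <- c(ids, sprintf("%s%04d", sub("[0-9]+$", "", named_ids[1]), 9000 + i))
    nms <- c(nms, sprintf("Synthetic set %d", i))
    ks <- c(ks, 7L + ((i * 3L) %% 11L))
  }
  ks[1] <- top_k
  data.frame(set_id = ids, set_name = nms, k = as.integer(ks),
             stringsAsFactors = FALSE)
}

#' Generate the deterministic formula-shaped fixture
#'
#' Writes a complete synthetic input bundle -- six per-herb compound
#' tables (seeded with the bundled 24 representative constituents),
#' a compound-target edge list (including sub-threshold predicted edges
#' and edges of inactive compounds as decoys), a disease gene list, GO
#' and pathway GMT collections with planted enrichment, and a pipeline
#' config with the 5-compound rescue whitelist -- engineered so that the
#' real pipeline stages reproduce every count pinned in the
#' \code{\link{fixture_spec}}. Generation is seed-deterministic:
#' identical spec and seed give byte-identical files.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param out_dir directory to write the fixture files into (created if
#'   needed).
#' @return a scenario list with \code{dir}, \code{files} (named paths)
#'   and \code{truth} (the expected stage counts and key node degrees).
#' @export
generate_paper_shape_fixture <- function(spec = fixture_spec(),
                                         out_dir = tempfile("fixture")) {
  validate_fixture_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  core <- wpx_representative_compounds()
  core_scr <- screen_compounds(core, screening_criteria(),
                               whitelist = core$mol_id)
  whitelist_ids <- sort(core_scr$rescued)
  n_unique <- sum(spec$per_herb) - spec$duplicates
  n_syn <- n_unique - nrow(core)
  n_active <- spec$screen_pass + length(whitelist_ids)
  n_final <- n_active - spec$targetless

  with_seed(spec$seed, {
    ## ---- compounds ---------------------------------------------------
    core_memberships <- unlist(strsplit(core$herbs, ","))
    remaining <- spec$per_herb - table(factor(core_memberships,
                                              levels = names(spec$per_herb)))
    n_dup_syn <- spec$duplicates - sum(grepl(",", core$herbs))
    syn_herbs <- assign_fixture_herbs(as.integer(remaining) |>
                                        setNames(names(spec$per_herb)),
                                      n_dup_syn, n_syn - n_dup_syn)
    syn_ids <- sprintf("MOLS%04d", seq_len(n_syn))
    n_pass_syn <- spec$screen_pass - length(core_scr$passed)
    is_pass <- seq_len(n_syn) <= n_pass_syn
    ob <- dl <- caco2 <- numeric(n_syn)
    ob[is_pass] <- round(runif(n_pass_syn, 30.5, 90), 2)
    dl[is_pass] <- round(runif(n_pass_syn, 0.19, 0.85), 2)
    caco2[is_pass] <- round(runif(n_pass_syn, 0.05, 1.5), 2)
    n_fail <- n_syn - n_pass_syn
    # cycle the 7 non-empty failure-mode combinations so the screen's
    # per-criterion flags are all exercised
    mode <- (seq_len(n_fail) - 1L) %% 7L + 1L
    f_ob <- mode %in% c(1L, 4L, 5L, 7L)
    f_dl <- mode %in% c(2L, 4L, 6L, 7L)
    f_c2 <- mode %in% c(3L, 5L, 6L, 7L)
    ob[!is_pass] <- round(ifelse(f_ob, runif(n_fail, 2, 29),
                                 runif(n_fail, 30.5, 90)), 2)
    dl[!is_pass] <- round(ifelse(f_dl, runif(n_fail, 0.01, 0.17),
                                 runif(n_fail, 0.19, 0.85)), 2)
    caco2[!is_pass] <- round(ifelse(f_c2, runif(n_fail, -1.5, -0.05),
                                    runif(n_fail, 0.05, 1.5)), 2)
    syn <- data.frame(mol_id = syn_ids,
                      name = sprintf("synthetic compound %d", seq_len(n_syn)),
                      herbs = syn_herbs, ob = ob, dl = dl, caco2 = caco2,
                      stringsAsFactors = FALSE)
    compounds <- rbind(core, syn)

    compound_files <- character(0)
    for (herb in names(spec$per_herb)) {
      in_herb <- vapply(strsplit(compounds$herbs, ","),
                        function(h) herb %in% h, logical(1))
      path <- file.path(out_dir, sprintf("compounds_%s.tsv", herb))
      write_compound_table(compounds[in_herb, , drop = FALSE], path)
      compound_files[herb] <- path
    }

    ## ---- genes and disease list --------------------------------------
    pools <- fixture_gene_pools(spec)
    disease_genes <- sample(c(pools$overlap, pools$disease_only))
    disease_path <- file.path(out_dir, "disease_genes.txt")
    writeLines(c("# synthetic disease gene list (gastric precancerous",
                 "# lesion shaped); one symbol per line",
                 disease_genes), disease_path)

    ## ---- compound-target edges ---------------------------------------
    syn_pass_ids <- syn_ids[is_pass]
    dropped_ids <- syn_pass_ids[seq.int(n_pass_syn - spec$targetless + 1L,
                                        n_pass_syn)]
    retained_ids <- sort(setdiff(c(core$mol_id, syn_pass_ids,
                                   whitelist_ids),
                                 c(dropped_ids, core_scr$rejected)))
    pinned <- fixture_pinned_degrees(spec)
    rest_ids <- sort(setdiff(retained_ids, names(pinned)))
    rest_total <- spec$ct_edges - sum(pinned)
    base <- rest_total %/% length(rest_ids)
    extra <- rest_total %% length(rest_ids)
    rest_deg <- rep(base, length(rest_ids)) +
      c(rep(1L, extra), rep(0L, length(rest_ids) - extra))
    degrees <- c(pinned, setNames(rest_deg, rest_ids))

    n_ov <- length(pools$overlap)
    pointer <- 0L
    main_edges <- vector("list", length(degrees))
    for (i in seq_along(degrees)) {
      w <- cyclic_window(pointer, degrees[[i]], n_ov)
      pointer <- w$pointer
      main_edges[[i]] <- data.frame(mol_id = names(degrees)[i],
                                    gene_symbol = pools$overlap[w$idx],
                                    stringsAsFactors = FALSE)
    }
    main_edges <- do.call(rbind, main_edges)
    i <- seq_len(nrow(main_edges))
    main_edges$source <- ifelse(i %% 2L == 0L, "curated", "predicted")
    main_edges$confidence <- ifelse(main_edges$source == "predicted",
                                    round(0.41 + ((i * 7L) %% 59L) / 100, 2),
                                    NA_real_)

    # target-less actives: edges only to non-disease targets, covering
    # the whole non-overlap side of the target universe
    n_no <- length(pools$nonoverlap)
    per_dropped <- ceiling(n_no / spec$targetless) + 1L
    pointer <- 0L
    drop_edges <- vector("list", spec$targetless)
    for (i in seq_len(spec$targetless)) {
      w <- cyclic_window(pointer, per_dropped, n_no)
      pointer <- w$pointer
      drop_edges[[i]] <- data.frame(mol_id = dropped_ids[i],
                                    gene_symbol = pools$nonoverlap[w$idx],
                                    source = "curated",
                                    confidence = NA_real_,
                                    stringsAsFactors = FALSE)
    }
    drop_edges <- do.call(rbind, drop_edges)

    # decoys: sub-threshold predictions (one exactly at the threshold,
    # which the strict cut must drop) and edges of inactive compounds
    n_decoy <- 30L
    low_conf <- data.frame(
      mol_id = rep_len(retained_ids, n_decoy),
      gene_symbol = rep_len(pools$disease_only, n_decoy),
      source = "predicted",
      confidence = c(0.40, round(runif(n_decoy - 1L, 0.05, 0.39), 2)),
      stringsAsFactors = FALSE)
    rejected_syn <- syn_ids[!is_pass]
    inactive <- data.frame(
      mol_id = rep_len(rejected_syn, n_decoy),
      gene_symbol = rep_len(pools$overlap, n_decoy),
      source = "curated", confidence = NA_real_,
      stringsAsFactors = FALSE)
    first_pred <- main_edges[main_edges$source == "predicted", ][1, ]
    dup_row <- transform(first_pred, confidence = 0.30)
    edges <- rbind(main_edges, drop_edges, low_conf, inactive, dup_row)
    edges_path <- file.path(out_dir, "edges.tsv")
    write_edge_list(edges, edges_path)

    ## ---- gene-set collections ----------------------------------------
    mapped <- pools$overlap[seq_len(spec$tp_targets)]
    leftovers <- setdiff(pools$overlap, mapped)
    pathway_plan <- fixture_set_plan(
      spec$pathways_retained, spec$top_pathway_overlap,
      named_ids = c("hsa05200", "hsa04151", "hsa04010", "hsa04014",
                    "hsa04668", "hsa04115", "hsa04110", "hsa04068",
                    "hsa04210", "hsa04066", "hsa04370", "hsa04064"),
      named_names = c("Pathways in cancer", "PI3K-Akt signaling pathway",
                      "MAPK signaling pathway", "Ras signaling pathway",
                      "TNF signaling pathway", "p53 signaling pathway",
                      "Cell cycle", "FoxO signaling pathway", "Apoptosis",
                      "HIF-1 signaling pathway", "VEGF signaling pathway",
                      "NF-kappa B signaling pathway"),
      named_ks = c(57L, 37L, 24L, 23L, 19L, 18L, 18L, 16L, 14L, 13L,
                   12L, 11L))
    pathway_gmt <- planted_collection(pathway_plan, mapped, leftovers,
                                      bg_prefix = "PBGG", bg_pool = 2000L,
                                      n_null = 25L, null_prefix = "PNULL")
    pathways_path <- file.path(out_dir, "pathways.gmt")
    write_gmt(pathway_gmt, pathways_path)

    go_plan <- fixture_set_plan(
      spec$go_retained, 30L,
      named_ids = c("GO:0045944", "GO:0043066", "GO:0006915",
                    "GO:0008284", "GO:0006954"),
      named_names = c(paste("positive regulation of transcription from",
                            "RNA polymerase II promoter"),
                      "negative regulation of apoptotic process",
                      "apoptotic process",
                      "positive regulation of cell proliferation",
                      "inflammatory response"),
      named_ks = c(30L, 28L, 25L, 24L, 22L))
    go_gmt <- planted_collection(go_plan, pools$overlap, character(0),
                                 bg_prefix = "GBGG", bg_pool = 1500L,
                                 n_null = 15L, null_prefix = "GONULL",
                                 null_query = pools$overlap)
    go_path <- file.path(out_dir, "go_bp.gmt")
    write_gmt(go_gmt, go_path)

    ## ---- config -------------------------------------------------------
    config <- pipeline_config(
      whitelist = setNames(
        rep("retained on established pharmacological activity",
            length(whitelist_ids)), whitelist_ids),
      modules = default_module_config()$mapping,
      seed = spec$seed)
    config_path <- file.path(out_dir, "config.yaml")
    write_pipeline_config(config, config_path)

    list(dir = out_dir,
         files = list(compounds = compound_files, edges = edges_path,
                      disease = disease_path, go_gmt = go_path,
                      pathway_gmt = pathways_path, config = config_path),
         truth = list(n_unique = n_unique,
                      n_duplicates = spec$duplicates,
                      n_passed = spec$screen_pass,
                      n_rescued = length(whitelist_ids),
                      n_active = n_active,
                      screen_yield_pct = round(100 * spec$screen_pass /
                                                 n_unique, 2),
                      target_universe = spec$target_universe,
                      disease_genes = spec$disease_genes,
                      overlap = spec$overlap,
                      n_final = n_final,
                      n_dropped = spec$targetless,
                      ct_nodes = n_final + spec$overlap,
                      ct_edges = spec$ct_edges,
                      mean_edges_per_compound = round(spec$ct_edges /
                                                        n_final, 2),
                      mean_degree_per_target = round(spec$ct_edges /
                                                       spec$overlap, 2),
                      hub_id = names(fixture_pinned_degrees(spec))[1],
                      hub_degree = spec$hub_degree,
                      pathways_retained = spec$pathways_retained,
                      tp_targets = spec$tp_targets,
                      top_pathway = pathway_plan$set_id[1],
                      top_pathway_degree = spec$top_pathway_overlap,
                      go_retained = spec$go_retained,
                      whitelist = whitelist_ids,
                      dropped_compounds = sort(dropped_ids)))
  })
}

# assemble a collection with planted sets (each half query, half
# background filler) plus weakly-overlapping large background sets that
# absorb the query genes outside the planted windows
planted_collection <- function(plan, window_genes, leftovers,
                               bg_prefix, bg_pool, n_null, null_prefix,
                               null_query = NULL) {
  bg <- sprintf("%s%04d", bg_prefix, seq_len(bg_pool))
  if (is.null(null_query)) null_query <- leftovers
  n_win <- length(window_genes)
  sets <- list()
  set_names <- character(0)
  pointer <- if (nrow(plan) > 1L) plan$k[1] %% n_win else 0L
  bg_ptr <- 0L
  take_bg <- function(k) {
    w <- cyclic_window(bg_ptr, k, bg_pool)
    bg_ptr <<- w$pointer
    bg[w$idx]
  }
  for (i in seq_len(nrow(plan))) {
    idx <- if (i == 1L) {
      seq_len(plan$k[1])
    } else {
      w <- cyclic_window(pointer, plan$k[i], n_win)
      pointer <- w$pointer
      w$idx
    }
    sets[[plan$set_id[i]]] <- c(window_genes[idx], take_bg(plan$k[i]))
    set_names[plan$set_id[i]] <- plan$set_name[i]
  }
  n_q <- length(null_query)
  for (j in seq_len(n_null)) {
    id <- sprintf("%s%03d", null_prefix, j)
    qidx <- ((2L * (j - 1L) + 0:1) %% n_q) + 1L
    sets[[id]] <- c(null_query[qidx], take_bg(148L))
    set_names[id] <- sprintf("Background set %d", j)
  }
  gene_set_collection(sets, set_names,
                      namespace = if (startsWith(bg_prefix, "G"))
                        "GO_BP" else "KEGG")
}

#' Generate a planted-enrichment scenario
#'
#' Builds a gene-set collection of \code{n_sets} random sets over a
#' synthetic universe and a query in which \code{n_planted} sets carry
#' \code{fold_enrichment} times their expected-by-chance number of query
#' members (placed exactly, by construction); the remaining query genes
#' are drawn from outside the planted sets, so the ground truth record
#' describes the generated query exactly. \code{fold_enrichment = 1}
#' yields a null scenario with a fully random query.
#'
#' @param n_sets number of gene sets.
#' @param set_size genes per set (sampled from the universe).
#' @param universe_size number of genes in the universe.
#' @param n_planted number of enriched sets (ignored when fold is 1).
#' @param fold_enrichment enrichment fold over the expected-by-chance
#'   overlap; must be >= 1.
#' @param query_size number of query genes.
#' @param seed integer seed; identical seeds give identical scenarios.
#' @return a list with \code{collection}, \code{query}, \code{universe},
#'   \code{truth} (\code{planted} ids, \code{planted_k},
#'   \code{expected}) and \code{params}.
#' @export
generate_enrichment_scenario <- function(n_sets = 40L, set_size = 200L,
                                         universe_size = 5000L,
                                         n_planted = 4L,
                                         fold_enrichment = 5,
                                         query_size = 50L, seed = 1L) {
  stopifnot(fold_enrichment >= 1, set_size <= universe_size)
  expected <- query_size * set_size / universe_size
  planted_k <- if (fold_enrichment > 1) ceiling(fold_enrichment * expected)
               else 0L
  if (planted_k > set_size) {
    stop(sprintf(paste0("infeasible fold: %d planted members per set ",
                        "exceed the set size %d"), planted_k, set_size),
         call. = FALSE)
  }
  if (fold_enrichment > 1 && n_planted * planted_k > query_size) {
    stop("infeasible fold: planted members exceed the query size",
         call. = FALSE)
  }
  with_seed(seed, {
    universe <- sprintf("U%05d", seq_len(universe_size))
    ids <- sprintf("SET%03d", seq_len(n_sets))
    sets <- setNames(lapply(ids, function(id) sample(universe, set_size)),
                     ids)
    collection <- gene_set_collection(sets, namespace = "other")
    if (fold_enrichment > 1) {
      planted <- ids[seq_len(n_planted)]
      chosen <- character(0)
      for (id in planted) {
        # draw from genes exclusive to this planted set, so each planted
        # set ends up with exactly planted_k query members
        others <- unlist(sets[setdiff(planted, id)], use.names = FALSE)
        pool <- setdiff(sets[[id]], c(chosen, others))
        if (length(pool) < planted_k) {
          stop("infeasible fold: planted sets overlap too heavily",
               call. = FALSE)
        }
        chosen <- c(chosen, sample(pool, planted_k))
      }
      outside <- setdiff(universe, unlist(sets[planted], use.names = FALSE))
      query <- c(chosen, sample(outside, query_size - length(chosen)))
    } else {
      planted <- character(0)
      query <- sample(universe, query_size)
    }
    list(collection = collection, query = query, universe = universe,
         truth = list(planted = planted, planted_k = planted_k,
                      expected = expected),
         params = list(n_sets = n_sets, set_size = set_size,
                       universe_size = universe_size,
                       n_planted = n_planted,
                       fold_enrichment = fold_enrichment,
                       query_size = query_size, seed = seed))
  })
}

#' Generate a synthetic drug-like reference descriptor table
#'
#' A stand-in for a drug-like reference database: non-negative molecular
#' descriptor values drawn per descriptor from log-normal distributions
#' with descriptor-specific location and scale (emulating the wildly
#' different natural scales of real molecular descriptors).
#'
#' @param n_molecules number of reference molecules (>= 2).
#' @param n_descriptors number of descriptor columns.
#' @param seed integer seed; identical seeds give identical tables.
#' @return a numeric matrix with rows \code{REF0001...} and columns
#'   \code{desc_01...}.
#' @export
generate_reference_descriptor_set <- function(n_molecules = 500L,
                                              n_descriptors = 12L,
                                              seed = 0L) {
  stopifnot(n_molecules >= 2L, n_descriptors >= 1L)
  with_seed(seed, {
    meanlog <- seq(-1, 4, length.out = n_descriptors)
    sdlog <- rep_len(c(0.3, 0.6, 1.0), n_descriptors)
    m <- vapply(seq_len(n_descriptors), function(j) {
      rlnorm(n_molecules, meanlog[j], sdlog[j])
    }, numeric(n_molecules))
    dimnames(m) <- list(sprintf("REF%04d", seq_len(n_molecules)),
                        sprintf("desc_%02d", seq_len(n_descriptors)))
    m
  })
}
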