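# Bipartite compound-target (C-T) and target-pathway (T-P) networks:
# construction, degree statistics, and Cytoscape-compatible export
# (GraphML / SIF / TSV edge list). Isolated nodes are excluded by
# construction: a node exists iff it carries at least one edge.

#' Construct a bipartite network from an edge table
#'
#' @param edges \code{data.frame} with two character columns (side-a
#'   node, side-b node); duplicate pairs are collapsed.
#' @param type_a,type_b node-type labels, e.g. \code{"compound"} and
#'   \code{"target"}.
#' @param name_a,name_b optional named character vectors mapping node
#'   ids to display names.
#' @return an object of class \code{bipartite_network}: list with
#'   \code{edges} (columns \code{from}, \code{to}), \code{side_a},
#'   \code{side_b}, \code{type_a}, \code{type_b}, \code{node_names}.
#' @export
bipartite_network <- function(edges, type_a, type_b,
                              name_a = NULL, name_b = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  keep <- !duplicated(paste(from, to, sep = "\r"))
  e <- data.frame(from = from[keep], to = to[keep],
                  stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  side_a <- sort(unique(e$from))
  side_b <- sort(unique(e$to))
  clash <- intersect(side_a, side_b)
  if (length(clash) > 0L) {
    stop(sprintf("node id(s) appear on both sides: %s",
                 paste(head(clash, 5), collapse = ", ")), call. = FALSE)
  }
  nn <- c(setNames(side_a, side_a), setNames(side_b, side_b))
  if (!is.null(name_a)) nn[intersect(side_a, names(name_a))] <-
    name_a[intersect(side_a, names(name_a))]
  if (!is.null(name_b)) nn[intersect(side_b, names(name_b))] <-
    name_b[intersect(side_b, names(name_b))]
  structure(list(edges = e, side_a = side_a, side_b = side_b,
                 type_a = type_a, type_b = type_b, node_names = nn),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d %s + %d %s nodes, %d edges\n",
              length(x$side_a), x$type_a, length(x$side_b), x$type_b,
              nrow(x$edges)))
  invisible(x)
}

#' Build the compound-target network
#'
#' Restricts the edge list to final compounds x overlap genes and builds
#' the bipartite C-T graph over exactly the compounds and genes with at
#' least one qualifying edge (no isolated nodes).
#'
#' @param final_compounds character vector of final (pruned) mol_ids.
#' @param overlap_genes character vector of disease-overlapping target
#'   symbols.
#' @param edges edge \code{data.frame} with \code{mol_id} and
#'   \code{gene_symbol} columns.
#' @param compound_names optional named vector mol_id -> display name.
#' @return a \code{bipartite_network} (compounds vs targets).
#' @export
build_ct_network <- function(final_compounds, overlap_genes, edges,
                             compound_names = NULL) {
  keep <- edges$mol_id %in% final_compounds &
    edges$gene_symbol %in% overlap_genes
  bipartite_network(edges[keep, c("mol_id", "gene_symbol"), drop = FALSE],
                    type_a = "compound", type_b = "target",
                    name_a = compound_names)
}

#' Build the target-pathway network
#'
#' An edge links a gene to a pathway iff the gene is an overlap target,
#' the pathway is retained by the enrichment filter, and the gene
#' belongs to the pathway's gene set. Genes lying in no retained pathway
#' are excluded.
#'
#' @param overlap_genes character vector of overlap target symbols.
#' @param retained_pathways an \code{\link{enrich}} result (its retained
#'   rows are used) or a character vector of retained set ids.
#' @param collection the \code{gene_set_collection} the pathways come
#'   from.
#' @return a \code{bipartite_network} (targets vs pathways).
#' @export
build_tp_network <- function(overlap_genes, retained_pathways, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- if (is.data.frame(retained_pathways)) {
    retained_pathways$set_id[retained_pathways$retained %||%
                               rep(TRUE, nrow(retained_pathways))]
  } else {
    as.character(retained_pathways)
  }
  ids <- intersect(ids, names(collection$sets))
  rows <- do.call(rbind, lapply(ids, function(id) {
    genes <- intersect(collection$sets[[id]], overlap_genes)
    if (length(genes) == 0L) return(NULL)
    data.frame(gene = genes, pathway = id, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(gene = character(0), pathway = character(0),
                       stringsAsFactors = FALSE)
  }
  bipartite_network(rows, type_a = "target", type_b = "pathway",
                    name_b = collection$set_names[ids])
}

#' Degree statistics of a bipartite network
#'
#' Per-node degrees, edge/node counts, side mean degrees (edge count
#' divided by side size, reported to two decimals) and the hub ranking
#' (degree descending, ties by node id ascending).
#'
#' @param net a \code{bipartite_network}.
#' @return an object of class \code{degree_report}: list with
#'   \code{degrees} (data.frame \code{node}, \code{side}, \code{type},
#'   \code{degree}), \code{n_nodes}, \code{n_edges},
#'   \code{mean_degree_side_a}, \code{mean_degree_side_b}, \code{hubs}.
#' @export
degree_statistics <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  n_edges <- nrow(net$edges)
  deg_a <- table(factor(net$edges$from, levels = net$side_a))
  deg_b <- table(factor(net$edges$to, levels = net$side_b))
  degrees <- data.frame(
    node = c(net$side_a, net$side_b),
    side = rep(c("a", "b"), c(length(net$side_a), length(net$side_b))),
    type = rep(c(net$type_a, net$type_b),
               c(length(net$side_a), length(net$side_b))),
    degree = as.integer(c(deg_a, deg_b)),
    stringsAsFactors = FALSE)
  hubs <- degrees[order(-degrees$degree, degrees$node), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(list(
    degrees = degrees,
    n_nodes = nrow(degrees),
    n_edges = n_edges,
    mean_degree_side_a = if (length(net$side_a) > 0L)
      round(n_edges / length(net$side_a), 2) else 0,
    mean_degree_side_b = if (length(net$side_b) > 0L)
      round(n_edges / length(net$side_b), 2) else 0,
    hubs = hubs), class = "degree_report")
}

#' @export
print.degree_report <- function(x, ...) {
  cat(sprintf(paste0("degree_report: %d nodes, %d edges; side means ",
                     "%.2f / %.2f\n"),
              x$n_nodes, x$n_edges, x$mean_degree_side_a,
              x$mean_degree_side_b))
  invisible(x)
}

as_igraph <- function(net) {
  deg <- degree_statistics(net)$degrees
  vertices <- data.frame(name = deg$node, node_type = deg$type,
                         degree = deg$degree,
                         label = unname(net$node_names[deg$node]),
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = vertices)
}

#' Export a bipartite network
#'
#' Writes the network as GraphML (with node-type, degree and label
#' attributes), SIF (\code{source interacts target}) or a TSV edge list.
#' Node and edge ordering is deterministic (type, then id), so repeated
#' export of the same network is byte-identical.
#'
#' @param net a \code{bipartite_network}.
#' @param path output file path.
#' @param format \code{"graphml"}, \code{"sif"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    writeLines(paste(net$edges$from, "interacts", net$edges$to), path)
  } else {
    out <- data.frame(source = net$edges$from, target = net$edges$to,
                      source_type = net$type_a, target_type = net$type_b,
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, eol = "\n")
  }
  invisible(path)
}

#' Re-import a GraphML export as a bipartite network
#'
#' @param path GraphML file written by \code{\link{export_network}}.
#' @return a \code{bipartite_network} isomorphic to the exported one,
#'   with node types and display names restored.
#' @export
import_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  types <- igraph::vertex_attr(g, "node_type")
  names(types) <- igraph::vertex_attr(g, "name")
  labels <- igraph::vertex_attr(g, "label")
  names(labels) <- names(types)
  type_levels <- unique(types[el[, 1]])
  if (length(type_levels) != 1L && nrow(el) > 0L) {
    # edges may be stored in either orientation; orient side a first
    swap <- types[el[, 1]] != types[el[1, 1]]
    el[swap, ] <- el[swap, c(2, 1)]
  }
  type_a <- if (nrow(el) > 0L) unname(types[el[1, 1]]) else "a"
  type_b <- if (nrow(el) > 0L) unname(types[el[1, 2]]) else "b"
  bipartite_network(data.frame(from = el[, 1], to = el[, 2],
                               stringsAsFactors = FALSE),
                    type_a = type_a, type_b = type_b,
                    name_a = labels, name_b = labels)
}
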