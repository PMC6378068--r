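# Compound->target map assembly: confidence filtering of predicted
# interactions, restriction to active compounds, intersection with the
# disease gene list, and pruning of compounds left without relevant
# targets.

#' Filter predicted edges by prediction confidence
#'
#' Predicted edges are kept iff their confidence is strictly greater
#' than \code{confidence_min} ("more than 40\%" at the default); curated
#' edges carry no prediction probability and are kept unconditionally.
#'
#' @param edges edge \code{data.frame} (see \code{\link{read_edge_list}}).
#' @param confidence_min strict lower bound in [0, 1].
#' @return the filtered edge \code{data.frame}.
#' @export
filter_predicted_edges <- function(edges, confidence_min = 0.40) {
  stopifnot(is.numeric(confidence_min), confidence_min >= 0,
            confidence_min <= 1)
  if (nrow(edges) == 0L) return(edges)
  keep <- edges$source == "curated" |
    (!is.na(edges$confidence) & edges$confidence > confidence_min)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the compound-target map over the active compounds
#'
#' Restricts a (confidence-filtered) edge list to active compounds,
#' deduplicates (mol_id, gene_symbol) pairs, and computes the target
#' universe: every gene symbol touched by at least one active compound.
#' If a \code{species} column is present, rows are first restricted to
#' \code{"Homo sapiens"} with a message reporting the dropped count.
#'
#' @param active character vector of active mol_ids.
#' @param edges edge \code{data.frame}, already confidence-filtered.
#' @return an object of class \code{target_map}: list with \code{edges},
#'   \code{target_universe} and \code{active}.
#' @export
build_target_map <- function(active, edges) {
  if ("species" %in% names(edges)) {
    n0 <- nrow(edges)
    edges <- edges[edges$species == "Homo sapiens", , drop = FALSE]
    if (nrow(edges) < n0) {
      message(sprintf("dropped %d non-human edge(s)", n0 - nrow(edges)))
    }
  }
  edges <- edges[edges$mol_id %in% active, , drop = FALSE]
  edges <- dedup_edges(edges)
  structure(list(edges = edges,
                 target_universe = sort(unique(edges$gene_symbol)),
                 active = unique(active)),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d edges, %d targets over %d active compounds\n",
              nrow(x$edges), length(x$target_universe), length(x$active)))
  invisible(x)
}

#' Intersect the target universe with a disease gene list
#'
#' The overlap genes are the compound-target universe intersected with
#' the disease genes; active compounds are then partitioned by whether
#' they retain at least one edge into the overlap.
#'
#' @param map a \code{target_map}.
#' @param disease a \code{disease_gene_list} or character vector of
#'   symbols.
#' @return an object of class \code{overlap_result}: list with
#'   \code{overlap_genes}, \code{retained_compounds},
#'   \code{dropped_compounds} and \code{overlap_edges} (edges into the
#'   overlap).
#' @export
intersect_disease_genes <- function(map, disease) {
  stopifnot(inherits(map, "target_map"))
  genes <- if (inherits(disease, "disease_gene_list")) disease$genes
           else normalize_symbols(disease)
  if (length(genes) == 0L) {
    warning("disease gene list is empty; overlap is empty", call. = FALSE)
  }
  overlap <- sort(intersect(map$target_universe, genes))
  hit <- map$edges$gene_symbol %in% overlap
  overlap_edges <- map$edges[hit, , drop = FALSE]
  rownames(overlap_edges) <- NULL
  retained <- unique(overlap_edges$mol_id)
  structure(list(overlap_genes = overlap,
                 retained_compounds = sort(retained),
                 dropped_compounds = sort(setdiff(map$active, retained)),
                 overlap_edges = overlap_edges),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("overlap_result: %d overlap genes; %d compounds ",
                     "retained, %d dropped\n"),
              length(x$overlap_genes), length(x$retained_compounds),
              length(x$dropped_compounds)))
  invisible(x)
}

#' Prune active compounds without disease-relevant targets
#'
#' Final compound selection: the active compounds that keep at least one
#' edge into the disease-overlapping targets; compounds with none are
#' discarded and reported.
#'
#' @param overlap an \code{overlap_result} computed from the active set.
#' @param active optional \code{screening_result} (or character vector)
#'   for a consistency check that the overlap was computed from the same
#'   active set.
#' @return list with \code{final_compounds}, \code{dropped_compounds}
#'   and their counts.
#' @export
prune_compounds <- function(overlap, active = NULL) {
  stopifnot(inherits(overlap, "overlap_result"))
  if (!is.null(active)) {
    ids <- if (inherits(active, "screening_result")) active_compounds(active)
           else as.character(active)
    expected <- sort(unique(ids))
    got <- sort(c(overlap$retained_compounds, overlap$dropped_compounds))
    if (!identical(expected, got)) {
      stop("overlap result was not computed from the given active set",
           call. = FALSE)
    }
  }
  list(final_compounds = overlap$retained_compounds,
       dropped_compounds = overlap$dropped_compounds,
       n_final = length(overlap$retained_compounds),
       n_dropped = length(overlap$dropped_compounds))
}
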