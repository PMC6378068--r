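# Integrated disease-pathway assembly: the FDR-retained pathways that
# survive curation are declared in a versioned module configuration
# (pathway id -> therapeutic module labels), and overlap targets inherit
# the union of their adjacent pathways' labels.

#' Module configuration for pathway curation
#'
#' Formalizes the curation step of pathway selection as a declarative
#' mapping from pathway id to one or more therapeutic-module labels, so
#' that which pathways enter the integrated disease pathway -- and why --
#' is versioned and testable rather than implicit.
#'
#' @param mapping named list: pathway id -> non-empty character vector
#'   of module labels.
#' @param vocabulary allowed module labels.
#' @return an object of class \code{module_config}.
#' @export
module_config <- function(mapping,
                          vocabulary = c("proliferation", "apoptosis",
                                         "inflammation")) {
  stopifnot(is.list(mapping))
  if (length(mapping) > 0L &&
      (is.null(names(mapping)) || any(!nzchar(names(mapping))))) {
    stop("module mapping must be named by pathway id", call. = FALSE)
  }
  mapping <- lapply(mapping, as.character)
  if (any(vapply(mapping, length, integer(1)) == 0L)) {
    stop("every mapped pathway needs at least one module label",
         call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(mapping)), vocabulary)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown module label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  structure(list(mapping = mapping, vocabulary = vocabulary),
            class = "module_config")
}

#' Default module configuration
#'
#' Encodes the nine key pathways of the integrated gastric
#' precancerous-lesion pathway and their therapeutic modules: pathways
#' in cancer (hsa05200, all three modules), PI3K-Akt (hsa04151) and
#' HIF-1 (hsa04066) signaling under proliferation, MAPK (hsa04010) under
#' proliferation and inflammation, Ras (hsa04014), FoxO (hsa04068) and
#' p53 (hsa04115) signaling under apoptosis, TNF signaling (hsa04668)
#' under apoptosis and inflammation, and NF-kappa B signaling (hsa04064)
#' under inflammation.
#'
#' @return a \code{module_config}.
#' @export
default_module_config <- function() {
  module_config(list(
    hsa05200 = c("proliferation", "apoptosis", "inflammation"),
    hsa04151 = "proliferation",
    hsa04010 = c("proliferation", "inflammation"),
    hsa04014 = "apoptosis",
    hsa04068 = "apoptosis",
    hsa04066 = "proliferation",
    hsa04668 = c("apoptosis", "inflammation"),
    hsa04115 = "apoptosis",
    hsa04064 = "inflammation"
  ))
}

#' Read a module configuration from YAML
#' @param path YAML file: top-level optional \code{vocabulary} list and
#'   a \code{modules} mapping pathway id -> list of labels.
#' @return a \code{module_config}.
#' @export
read_module_config <- function(path) {
  y <- yaml::read_yaml(path)
  vocab <- unlist(y$vocabulary) %||%
    c("proliferation", "apoptosis", "inflammation")
  module_config(y$modules %||% list(), vocabulary = vocab)
}

#' Write a module configuration to YAML
#' @param config a \code{module_config}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_module_config <- function(config, path) {
  yaml::write_yaml(list(vocabulary = as.list(config$vocabulary),
                        modules = lapply(config$mapping, as.list)), path)
  invisible(path)
}

#' Assign retained pathways to therapeutic modules
#'
#' Pathways present in both the retained enrichment set and the module
#' configuration keep their labels; retained pathways absent from the
#' configuration are listed as unassigned (they are not errors -- they
#' simply do not enter the integrated pathway).
#'
#' @param retained an \code{\link{enrich}} result (retained rows used)
#'   or character vector of retained pathway ids.
#' @param config a \code{module_config}.
#' @return an object of class \code{integrated_pathway} (skeleton):
#'   list with \code{pathways} (data.frame \code{set_id},
#'   \code{modules}), \code{unassigned}, \code{config}.
#' @export
assign_modules <- function(retained, config) {
  stopifnot(inherits(config, "module_config"))
  ids <- if (is.data.frame(retained)) {
    retained$set_id[retained$retained %||% rep(TRUE, nrow(retained))]
  } else {
    as.character(retained)
  }
  if (length(ids) == 0L) stop("no retained pathways to assign", call. = FALSE)
  assigned <- intersect(ids, names(config$mapping))
  pathways <- data.frame(
    set_id = assigned,
    modules = vapply(assigned, function(id)
      paste(sort(unique(config$mapping[[id]])), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  rownames(pathways) <- NULL
  structure(list(pathways = pathways,
                 unassigned = sort(setdiff(ids, assigned)),
                 config = config,
                 targets = NULL),
            class = "integrated_pathway")
}

#' Build the integrated disease pathway
#'
#' Annotates each target of the target-pathway network with the union of
#' the module labels of its adjacent module-assigned pathways. Targets
#' adjacent only to unassigned pathways are excluded. The result is
#' deterministic and fully determined by the network and configuration.
#'
#' @param tp_net the target-pathway \code{bipartite_network}.
#' @param skeleton the \code{integrated_pathway} skeleton from
#'   \code{\link{assign_modules}}; its pathways must be nodes of
#'   \code{tp_net}.
#' @return the completed \code{integrated_pathway}: adds \code{targets}
#'   (data.frame \code{gene}, \code{modules}) and \code{edges} (the
#'   target-pathway edges restricted to assigned pathways).
#' @export
build_integrated_pathway <- function(tp_net, skeleton) {
  stopifnot(inherits(tp_net, "bipartite_network"),
            inherits(skeleton, "integrated_pathway"))
  missing <- setdiff(skeleton$pathways$set_id, tp_net$side_b)
  if (length(missing) > 0L) {
    stop(sprintf("pathway(s) absent from the target-pathway network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  labels_of <- setNames(strsplit(skeleton$pathways$modules, ";", fixed = TRUE),
                        skeleton$pathways$set_id)
  keep <- tp_net$edges$to %in% skeleton$pathways$set_id
  edges <- tp_net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  genes <- sort(unique(edges$from))
  targets <- data.frame(
    gene = genes,
    modules = vapply(genes, function(g) {
      paste(sort(unique(unlist(labels_of[edges$to[edges$from == g]]))),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(targets) <- NULL
  out <- skeleton
  out$targets <- targets
  out$edges <- edges
  out
}

#' @export
print.integrated_pathway <- function(x, ...) {
  cat(sprintf("integrated_pathway: %d module-assigned pathways (%d unassigned)",
              nrow(x$pathways), length(x$unassigned)))
  if (!is.null(x$targets)) {
    cat(sprintf(", %d annotated targets", nrow(x$targets)))
  }
  cat("\n")
  invisible(x)
}

#' Write the integrated-pathway annotation tables
#'
#' @param integrated a completed \code{integrated_pathway}.
#' @param path output TSV path for the target annotation table.
#' @return \code{path}, invisibly.
#' @export
write_integrated_annotation <- function(integrated, path) {
  stopifnot(!is.null(integrated$targets))
  write.table(integrated$targets, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
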