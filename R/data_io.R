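# Readers/writers for every external format the pipeline touches: TSV
# compound tables, TSV compound->target edge lists, GMT gene-set
# collections, plain-text gene lists, and the YAML pipeline config.
# The canonical table dialect is tab-separated UTF-8 with a header row,
# so free-text compound names containing commas are safe.

# Numeric parser for database-exported ADME columns. Some exports print
# negatives in accountant style, e.g. "(2.22)" for -2.22; those are
# converted before coercion.
parse_adme_numeric <- function(x, column, path) {
  x <- trimws(as.character(x))
  paren <- grepl("^\\(.*\\)$", x)
  x[paren] <- paste0("-", sub("^\\((.*)\\)$", "\\1", x[paren]))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(is.na(x) | x == "" | x == "NA"))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' in column '%s' at data row %d of %s",
                 x[bad[1]], column, bad[1], path), call. = FALSE)
  }
  out
}

#' Read a per-herb compound table
#'
#' Parses a tab-separated compound table (one row per molecule) into a
#' validated herb compound list. Mandatory columns are \code{mol_id},
#' \code{name}, \code{ob} (oral bioavailability, percent), \code{dl}
#' (drug-likeness index) and \code{caco2} (Caco-2 permeability score; may
#' be negative, and parenthesized negatives such as \code{(2.22)} are
#' accepted). Columns prefixed \code{desc_} are collected as molecular
#' descriptor values. Row order is preserved.
#'
#' @param path path to a TSV file with a header row.
#' @param herb_code short code of the herb the table belongs to,
#'   e.g. \code{"HMM"}.
#' @return a \code{data.frame} of class \code{herb_compound_list} with
#'   columns \code{mol_id}, \code{name}, \code{herbs}, \code{ob},
#'   \code{dl}, \code{caco2} and any \code{desc_*} columns, plus a
#'   \code{herb_code} attribute.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("mol_id\tname\tob\tdl\tcaco2",
#'              "MOL000006\tLuteolin\t36.16\t0.25\t0.19"), tsv)
#' read_compound_table(tsv, "PHP")
#' @export
read_compound_table <- function(path, herb_code) {
  stopifnot(is.character(path), length(path) == 1L,
            is.character(herb_code), length(herb_code) == 1L)
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "", comment.char = "",
                    stringsAsFactors = FALSE)
  required <- c("mol_id", "name", "ob", "dl", "caco2")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("compound table %s is missing mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(mol_id = trimws(raw$mol_id),
                    name = trimws(raw$name),
                    herbs = rep(herb_code, nrow(raw)),
                    ob = parse_adme_numeric(raw$ob, "ob", path),
                    dl = parse_adme_numeric(raw$dl, "dl", path),
                    caco2 = parse_adme_numeric(raw$caco2, "caco2", path),
                    stringsAsFactors = FALSE)
  if ("herbs" %in% names(raw)) out$herbs <- trimws(raw$herbs)
  dup <- out$mol_id[duplicated(out$mol_id)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate mol_id within %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (any(out$ob < 0, na.rm = TRUE)) {
    stop(sprintf("negative oral bioavailability in %s", path), call. = FALSE)
  }
  out_of_range <- !is.na(out$dl) & (out$dl < 0 | out$dl > 1)
  if (any(out_of_range)) {
    warning(sprintf("%d dl value(s) outside [0, 1] in %s (accepted as-is)",
                    sum(out_of_range), path), call. = FALSE)
  }
  desc_cols <- grep("^desc_", names(raw), value = TRUE)
  for (dc in desc_cols) out[[dc]] <- parse_adme_numeric(raw[[dc]], dc, path)
  class(out) <- c("herb_compound_list", "data.frame")
  attr(out, "herb_code") <- herb_code
  out
}

#' Write a compound table to TSV
#'
#' Inverse of \code{\link{read_compound_table}}; writing then re-reading
#' reproduces the parsed records exactly.
#'
#' @param x a compound table (per-herb list or merged table).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_compound_table <- function(x, path) {
  cols <- intersect(c("mol_id", "name", "herbs", "ob", "dl", "caco2",
                      grep("^desc_", names(x), value = TRUE),
                      setdiff(names(x), c("mol_id", "name", "herbs", "ob",
                                          "dl", "caco2"))), names(x))
  write.table(as.data.frame(x)[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a compound-target edge list
#'
#' Parses a TSV with columns \code{mol_id}, \code{gene_symbol},
#' \code{source} (\code{curated} or \code{predicted}) and an optional
#' \code{confidence} column (prediction probability in [0, 1], mandatory
#' for predicted edges). Gene symbols are normalized to uppercase and
#' duplicate (mol_id, gene_symbol) pairs are collapsed keeping the
#' maximum confidence; a pair that is curated in any duplicate stays
#' curated.
#'
#' @param path path to the TSV edge list.
#' @return a \code{data.frame} with columns \code{mol_id},
#'   \code{gene_symbol}, \code{source}, \code{confidence} (NA for
#'   curated edges).
#' @export
read_edge_list <- function(path) {
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "", stringsAsFactors = FALSE)
  required <- c("mol_id", "gene_symbol", "source")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("edge list %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  src <- trimws(raw$source)
  bad_src <- setdiff(unique(src), c("curated", "predicted"))
  if (length(bad_src) > 0L) {
    stop(sprintf("unknown edge source(s) in %s: %s", path,
                 paste(bad_src, collapse = ", ")), call. = FALSE)
  }
  conf <- if ("confidence" %in% names(raw)) {
    parse_adme_numeric(raw$confidence, "confidence", path)
  } else {
    rep(NA_real_, nrow(raw))
  }
  no_conf <- src == "predicted" & is.na(conf)
  if (any(no_conf)) {
    stop(sprintf("predicted edge without confidence at data row %d of %s",
                 which(no_conf)[1], path), call. = FALSE)
  }
  out_of_range <- !is.na(conf) & (conf < 0 | conf > 1)
  if (any(out_of_range)) {
    stop(sprintf("confidence outside [0, 1] at data row %d of %s",
                 which(out_of_range)[1], path), call. = FALSE)
  }
  edges <- data.frame(mol_id = trimws(raw$mol_id),
                      gene_symbol = normalize_symbols(raw$gene_symbol),
                      source = src, confidence = conf,
                      stringsAsFactors = FALSE)
  dedup_edges(edges)
}

# collapse duplicate (mol_id, gene_symbol) pairs: keep max confidence,
# and 'curated' wins over 'predicted'
dedup_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  key <- paste(edges$mol_id, edges$gene_symbol, sep = "\r")
  if (!anyDuplicated(key)) {
    rownames(edges) <- NULL
    return(edges)
  }
  keep <- split(seq_len(nrow(edges)), key)
  rows <- vapply(keep, function(idx) {
    if (length(idx) == 1L) return(idx)
    cur <- idx[edges$source[idx] == "curated"]
    if (length(cur) > 0L) return(cur[1])
    idx[which.max(edges$confidence[idx])]
  }, integer(1))
  conf_max <- vapply(keep, function(idx) {
    v <- edges$confidence[idx]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  out <- edges[rows, , drop = FALSE]
  out$confidence <- ifelse(out$source == "predicted", conf_max, out$confidence)
  out <- out[order(match(rows, seq_len(nrow(edges)))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edge list to TSV
#' @param edges edge \code{data.frame} as returned by
#'   \code{\link{read_edge_list}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  out <- edges[, c("mol_id", "gene_symbol", "source", "confidence")]
  out$confidence <- ifelse(is.na(out$confidence), "",
                           format(out$confidence, trim = TRUE, digits = 15))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set_id -> member genes).
#' @param set_names optional named character vector of descriptions.
#' @param namespace one of \code{"GO_BP"}, \code{"KEGG"}, \code{"other"}.
#' @return an object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, set_names = NULL,
                                namespace = c("other", "GO_BP", "KEGG")) {
  namespace <- match.arg(namespace)
  stopifnot(is.list(sets))
  ids <- names(sets)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("gene sets must have unique set_id names", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(normalize_symbols(g)))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    stop(sprintf("empty gene set(s): %s",
                 paste(ids[empty], collapse = ", ")), call. = FALSE)
  }
  if (is.null(set_names)) set_names <- setNames(ids, ids)
  structure(list(namespace = namespace, sets = sets,
                 set_names = set_names[ids]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection [%s]: %d sets, %d distinct genes\n",
              x$namespace, length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line,
#' \code{set_id TAB description TAB gene TAB gene ...}. Genes are
#' uppercased and deduplicated per set.
#'
#' @param path path to the GMT file.
#' @param namespace collection namespace label (see
#'   \code{\link{gene_set_collection}}).
#' @return a \code{gene_set_collection}.
#' @export
read_gmt <- function(path, namespace = "other") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_set_collection(setNames(list(), character(0)),
                               namespace = namespace))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    stop(sprintf("GMT line %d of %s has fewer than 3 tab-separated fields",
                 which(short)[1], path), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  gene_set_collection(setNames(genes, ids), setNames(descs, ids), namespace)
}

#' Write a gene-set collection to GMT
#' @param collection a \code{gene_set_collection}.
#' @param path output GMT path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(collection, path) {
  ids <- names(collection$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$set_names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and lines starting with \code{#} are
#' ignored; symbols are trimmed and uppercased. An empty result is valid
#' and produces a warning, not an error.
#'
#' @param path path to the gene list file.
#' @param label free-text label for the list (e.g. the disease name).
#' @return an object of class \code{disease_gene_list} with elements
#'   \code{disease_label} and \code{genes}.
#' @export
read_gene_list <- function(path, label = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(normalize_symbols(lines))
  if (length(genes) == 0L) {
    warning(sprintf("gene list %s is empty", path), call. = FALSE)
  }
  structure(list(disease_label = label, genes = genes),
            class = "disease_gene_list")
}

#' Write a gene list
#' @param genes character vector or \code{disease_gene_list}.
#' @param path output path, one symbol per line.
#' @return \code{path}, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  if (inherits(genes, "disease_gene_list")) genes <- genes$genes
  writeLines(genes, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Screening thresholds follow the integrative ADME screen (oral
#' bioavailability >= 30\%, drug-likeness >= 0.18, Caco-2 >= 0); predicted
#' compound-target edges require a prediction probability strictly above
#' 0.40; gene sets are retained at BH-FDR strictly below 0.01.
#'
#' @param ob_min,dl_min,caco2_min inclusive screening floors.
#' @param confidence_min strict lower bound for predicted-edge confidence.
#' @param fdr_max strict upper bound for the BH-adjusted q-value.
#' @param whitelist named character vector: mol_id -> free-text rationale
#'   for rescuing a compound that fails the screen.
#' @param universe enrichment background policy: \code{"collection"}
#'   (union of all genes in the loaded collection) or a character vector
#'   of symbols.
#' @param modules named list mapping pathway ids to module labels (see
#'   \code{\link{module_config}}); \code{NULL} uses
#'   \code{\link{default_module_config}}.
#' @param seed integer seed recorded in run reports.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(ob_min = 30, dl_min = 0.18, caco2_min = 0,
                            confidence_min = 0.40, fdr_max = 0.01,
                            whitelist = character(0),
                            universe = "collection", modules = NULL,
                            seed = 0L) {
  thresholds <- c(ob_min = ob_min, dl_min = dl_min, caco2_min = caco2_min,
                  confidence_min = confidence_min)
  if (!all(is.finite(thresholds))) {
    stop("all screening thresholds must be finite", call. = FALSE)
  }
  if (!is.numeric(fdr_max) || fdr_max <= 0 || fdr_max > 1) {
    stop("fdr_max must be in (0, 1]", call. = FALSE)
  }
  structure(list(ob_min = ob_min, dl_min = dl_min, caco2_min = caco2_min,
                 confidence_min = confidence_min, fdr_max = fdr_max,
                 whitelist = whitelist, universe = universe,
                 modules = modules, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: \code{screening} (\code{ob_min},
#' \code{dl_min}, \code{caco2_min}), \code{confidence_min},
#' \code{fdr_max}, \code{whitelist} (mapping mol_id -> rationale),
#' \code{universe}, \code{modules} (mapping pathway id -> list of module
#' labels) and \code{seed}. Missing keys take the defaults of
#' \code{\link{pipeline_config}}.
#'
#' @param path path to the YAML config file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scr <- y$screening %||% list()
  wl <- y$whitelist %||% character(0)
  if (is.list(wl)) wl <- unlist(wl)
  pipeline_config(
    ob_min = scr$ob_min %||% 30,
    dl_min = scr$dl_min %||% 0.18,
    caco2_min = scr$caco2_min %||% 0,
    confidence_min = y$confidence_min %||% 0.40,
    fdr_max = y$fdr_max %||% 0.01,
    whitelist = wl,
    universe = y$universe %||% "collection",
    modules = y$modules,
    seed = y$seed %||% 0L
  )
}

#' Write a pipeline configuration to YAML
#' @param config a \code{pipeline_config}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  y <- list(
    screening = list(ob_min = config$ob_min, dl_min = config$dl_min,
                     caco2_min = config$caco2_min),
    confidence_min = config$confidence_min,
    fdr_max = config$fdr_max,
    whitelist = as.list(config$whitelist),
    universe = config$universe,
    modules = config$modules,
    seed = config$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Hash of the semantic fields of a pipeline config
#'
#' The hash changes iff any semantic config field changes, which makes
#' run reports auditable against the config that produced them.
#'
#' @param config a \code{pipeline_config}.
#' @return an md5 string.
#' @export
config_hash <- function(config) {
  fields <- config[c("ob_min", "dl_min", "caco2_min", "confidence_min",
                     "fdr_max", "whitelist", "universe", "modules", "seed")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Bundled table of representative formula constituents
#'
#' Returns the packaged table of 24 representative constituents of the
#' six-herb Wei Pi Xiao decoction with their database-reported oral
#' bioavailability, drug-likeness and Caco-2 permeability values and herb
#' provenance. Nineteen of the rows satisfy the default ADME screen; the
#' other five (atractylenolide I, oleanolic acid, astragaloside IV,
#' curcumol, danshensu) fail at least one criterion and are the classic
#' whitelist-rescue examples.
#'
#' @return a merged compound table (\code{data.frame}).
#' @export
wpx_representative_compounds <- function() {
  path <- system.file("extdata", "wpx_representative_compounds.tsv",
                      package = "netpharm", mustWork = TRUE)
  tab <- read_compound_table(path, herb_code = "WPX")
  class(tab) <- "data.frame"
  attr(tab, "herb_code") <- NULL
  tab
}
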