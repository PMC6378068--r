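# Over-representation analysis of a query gene set against a gene-set
# collection: one-sided Fisher's exact test (hypergeometric upper tail)
# per set, Benjamini-Hochberg FDR across all tested sets, strict
# retention at fdr < fdr_max.

#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value: \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)} -- the probability of
#' drawing at least \code{k} members of a size-\code{K} set when drawing
#' \code{n} genes from a universe of \code{N}. Equivalent to the
#' one-sided (greater) Fisher's exact test on the 2x2 overlap table.
#' Computed via \code{stats::phyper}, which sums the exact tail in log
#' space; \code{k = 0} returns exactly 1.
#'
#' @param k observed overlap count (vectorized).
#' @param K gene-set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  args <- cbind(k = k, K = K, n = n, N = N)
  k <- args[, "k"]; K <- args[, "K"]; n <- args[, "n"]; N <- args[, "N"]
  if (any(K > N) || any(n > N)) {
    stop("set size and query size cannot exceed the universe size",
         call. = FALSE)
  }
  if (any(k > pmin(K, n)) || any(k < 0)) {
    stop("impossible overlap configuration: k must lie in [0, min(K, n)]",
         call. = FALSE)
  }
  unname(phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, returned in the input
#' order (a thin wrapper over \code{stats::p.adjust(method = "BH")}).
#' The result is permutation-equivariant and monotone in p-value rank.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in the same order; empty input gives empty output.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis with FDR control
#'
#' Tests every gene set with at least one query member for
#' over-representation of the query within the universe, using the
#' hypergeometric upper tail; q-values are Benjamini-Hochberg adjusted
#' across all tested sets, and sets are retained iff
#' \code{fdr < fdr_max} (strict). Query genes outside the universe are
#' dropped with a message. The default universe is the union of all
#' genes in the collection (annotation-background convention).
#'
#' @param query character vector of gene symbols.
#' @param collection a \code{\link{gene_set_collection}}.
#' @param universe background gene symbols; \code{NULL} for the union of
#'   the collection's genes.
#' @param fdr_max strict retention threshold on the q-value.
#' @return a \code{data.frame} sorted by ascending p-value (ties broken
#'   by set_id) with columns \code{set_id}, \code{set_name}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p_value}, \code{fdr},
#'   \code{retained}.
#' @export
enrich <- function(query, collection, universe = NULL, fdr_max = 0.01) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(universe)) {
    universe <- unique(unlist(collection$sets, use.names = FALSE))
  } else {
    universe <- unique(normalize_symbols(universe))
  }
  if (length(universe) == 0L) {
    stop("enrichment universe is empty", call. = FALSE)
  }
  query <- unique(normalize_symbols(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    message(sprintf("dropping %d query gene(s) outside the universe",
                    length(outside)))
    query <- setdiff(query, outside)
  }
  empty <- data.frame(set_id = character(0), set_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), retained = logical(0),
                      stringsAsFactors = FALSE)
  if (length(query) == 0L) {
    warning("empty query; no enrichment computed", call. = FALSE)
    return(empty)
  }
  N <- length(universe)
  n <- length(query)
  ids <- names(collection$sets)
  k <- vapply(collection$sets, function(g) length(intersect(g, query)),
              integer(1))
  K <- vapply(collection$sets, function(g) length(intersect(g, universe)),
              integer(1))
  tested <- k >= 1L
  if (!any(tested)) return(empty)
  res <- data.frame(set_id = ids[tested],
                    set_name = unname(collection$set_names[ids[tested]]),
                    k = unname(k[tested]), K = unname(K[tested]),
                    n = n, N = N, stringsAsFactors = FALSE)
  res$p_value <- hypergeometric_tail(res$k, res$K, res$n, res$N)
  res$fdr <- bh_fdr(res$p_value)
  res$retained <- res$fdr < fdr_max
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "fdr_max") <- fdr_max
  res
}

#' Retained sets of an enrichment result
#' @param result a \code{data.frame} from \code{\link{enrich}}.
#' @return the rows with \code{retained == TRUE}.
#' @export
retained_sets <- function(result) {
  out <- result[result$retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}
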