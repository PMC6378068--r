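# Integrative ADME screen: drug-likeness as a Tanimoto index of a
# compound's (min-max scaled) molecular descriptor vector against the
# mean descriptor vector of a drug-like reference set, combined with
# oral-bioavailability and Caco-2 permeability floors and a whitelist
# rescue for pharmacologically established compounds.

#' Compute a reference descriptor profile
#'
#' Min-max scales each descriptor over the reference set, then takes the
#' component-wise mean of the scaled reference vectors as the reference
#' profile (the "average drug" vector drug-likeness is measured against).
#' The scaling parameters are retained so that query compounds are mapped
#' onto the same [0, 1] scale.
#'
#' @param reference_table numeric matrix or data.frame of reference
#'   molecules (rows) by descriptors (columns); at least 2 rows, all
#'   values non-negative.
#' @return a list of class \code{reference_profile} with
#'   \code{descriptor_names}, \code{b_vector} (scaled reference mean) and
#'   \code{scaling_params} (per-descriptor min/max).
#' @seealso \code{\link{compute_dl}}, \code{\link{scale_descriptors}}
#' @export
compute_reference_profile <- function(reference_table) {
  m <- as.matrix(reference_table)
  if (nrow(m) < 2L) {
    stop("reference set must contain at least 2 molecules", call. = FALSE)
  }
  if (is.null(colnames(m))) {
    stop("reference table must have named descriptor columns", call. = FALSE)
  }
  storage.mode(m) <- "double"
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  scaled <- scale_matrix_minmax(m, mins, maxs)
  structure(list(descriptor_names = colnames(m),
                 b_vector = colMeans(scaled),
                 scaling_params = list(min = mins, max = maxs)),
            class = "reference_profile")
}

scale_matrix_minmax <- function(m, mins, maxs) {
  rng <- maxs - mins
  out <- sweep(m, 2, mins, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Scale a raw descriptor vector against a reference profile
#'
#' Maps each component by \code{(x - min) / (max - min)} using the
#' reference-set min/max, then clamps to [0, 1]. A degenerate descriptor
#' (constant over the reference set) maps to 0 with a warning.
#'
#' @param raw named numeric vector with the profile's descriptor names.
#' @param profile a \code{reference_profile}.
#' @return scaled numeric vector in [0, 1], in profile descriptor order.
#' @export
scale_descriptors <- function(raw, profile) {
  nm <- profile$descriptor_names
  unknown <- setdiff(names(raw), nm)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown descriptor name(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!all(nm %in% names(raw))) {
    stop(sprintf("missing descriptor(s): %s",
                 paste(setdiff(nm, names(raw)), collapse = ", ")),
         call. = FALSE)
  }
  x <- as.numeric(raw[nm])
  mins <- profile$scaling_params$min
  maxs <- profile$scaling_params$max
  rng <- maxs - mins
  if (any(rng == 0)) {
    warning(sprintf("constant reference descriptor(s) map to 0: %s",
                    paste(nm[rng == 0], collapse = ", ")), call. = FALSE)
  }
  out <- (x - mins) / ifelse(rng == 0, 1, rng)
  out[rng == 0] <- 0
  setNames(pmin(pmax(out, 0), 1), nm)
}

#' Tanimoto drug-likeness index
#'
#' Computes the drug-likeness of a compound as the Tanimoto similarity
#' \deqn{T(A, B) = \frac{A \cdot B}{\|A\|^2 + \|B\|^2 - A \cdot B}}
#' between the compound's scaled descriptor vector \eqn{A} and the
#' reference-profile mean vector \eqn{B}. For non-negative vectors the
#' index lies in [0, 1], is symmetric, and equals 1 iff \eqn{A = B}
#' (non-zero). Two all-zero vectors return 0 by convention.
#'
#' @param a scaled descriptor vector of the compound (non-negative).
#' @param profile a \code{reference_profile}, or a plain non-negative
#'   numeric vector to compare against directly.
#' @return the drug-likeness index, a scalar in [0, 1].
#' @examples
#' compute_dl(c(1, 2, 2), c(2, 1, 0))  # 4 / (9 + 5 - 4) = 0.4
#' @export
compute_dl <- function(a, profile) {
  b <- if (inherits(profile, "reference_profile")) profile$b_vector else profile
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("descriptor vectors have mismatched dimensions", call. = FALSE)
  }
  if (any(a < 0) || any(b < 0)) {
    stop("Tanimoto drug-likeness requires non-negative components",
         call. = FALSE)
  }
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) return(0)
  ab / denom
}

#' Merge per-herb compound lists into one formula-level table
#'
#' Compounds sharing a \code{mol_id} across herbs are merged into a
#' single record whose herb set is the union (the herbs column joins
#' codes with commas). ADME values of duplicates must agree to within
#' \code{tol} (they originate from a single database); disagreement is a
#' conflict error naming the mol_id.
#'
#' @param lists list of \code{herb_compound_list} tables.
#' @param tol maximum allowed absolute ADME discrepancy between
#'   duplicate records.
#' @return a merged compound table (\code{data.frame}) with one row per
#'   unique mol_id, in first-appearance order, with attribute
#'   \code{n_duplicates} (number of cross-herb duplicate memberships
#'   removed).
#' @export
merge_herb_lists <- function(lists, tol = 1e-9) {
  stopifnot(length(lists) >= 1L)
  all_rows <- do.call(rbind, lapply(lists, function(x) {
    as.data.frame(x)[, c("mol_id", "name", "herbs", "ob", "dl", "caco2"),
                     drop = FALSE]
  }))
  split_idx <- split(seq_len(nrow(all_rows)), all_rows$mol_id)
  for (idx in split_idx) {
    if (length(idx) > 1L) {
      for (col in c("ob", "dl", "caco2")) {
        v <- all_rows[[col]][idx]
        if (diff(range(v)) > tol) {
          stop(sprintf("conflicting %s values for duplicate mol_id %s",
                       col, all_rows$mol_id[idx[1]]), call. = FALSE)
        }
      }
    }
  }
  first <- !duplicated(all_rows$mol_id)
  merged <- all_rows[first, , drop = FALSE]
  herbs <- vapply(split_idx, function(idx) {
    paste(sort(unique(unlist(strsplit(all_rows$herbs[idx], ",")))),
          collapse = ",")
  }, character(1))
  merged$herbs <- unname(herbs[merged$mol_id])
  rownames(merged) <- NULL
  attr(merged, "n_duplicates") <- nrow(all_rows) - nrow(merged)
  merged
}

#' Screening criteria for the integrative ADME screen
#' @param ob_min oral bioavailability floor, percent (inclusive).
#' @param dl_min drug-likeness floor (inclusive).
#' @param caco2_min Caco-2 permeability floor (inclusive).
#' @return a list of class \code{screening_criteria}.
#' @export
screening_criteria <- function(ob_min = 30, dl_min = 0.18, caco2_min = 0) {
  v <- c(ob_min = ob_min, dl_min = dl_min, caco2_min = caco2_min)
  if (!all(is.finite(v))) stop("criteria must be finite", call. = FALSE)
  structure(as.list(v), class = "screening_criteria")
}

#' Three-criterion ADME screen with whitelist rescue
#'
#' A compound passes iff \code{ob >= ob_min} and \code{dl >= dl_min} and
#' \code{caco2 >= caco2_min} (all floors inclusive). Compounds failing at
#' least one criterion but present on the whitelist are rescued (retained
#' as active on pharmacological grounds); the remainder are rejected with
#' per-criterion failure flags. Passed, rescued and rejected partition
#' the input, and the active set is passed plus rescued.
#'
#' @param table merged compound table (see \code{\link{merge_herb_lists}}).
#' @param criteria a \code{\link{screening_criteria}}.
#' @param whitelist character vector of mol_ids to rescue (names, if
#'   any, are free-text rationales).
#' @return an object of class \code{screening_result}: list with
#'   \code{table} (input plus \code{status} and \code{failed_criteria}
#'   columns), \code{passed}, \code{rescued}, \code{rejected} (mol_id
#'   vectors) and \code{criteria}.
#' @export
screen_compounds <- function(table, criteria = screening_criteria(),
                             whitelist = character(0)) {
  stopifnot(all(c("mol_id", "ob", "dl", "caco2") %in% names(table)))
  wl_ids <- if (!is.null(names(whitelist)) && any(nzchar(names(whitelist))))
    names(whitelist) else as.character(whitelist)
  absent <- setdiff(wl_ids, table$mol_id)
  if (length(absent) > 0L) {
    warning(sprintf("whitelist mol_id(s) absent from table: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  fail_ob <- !(table$ob >= criteria$ob_min)
  fail_dl <- !(table$dl >= criteria$dl_min)
  fail_caco2 <- !(table$caco2 >= criteria$caco2_min)
  n_fail <- fail_ob + fail_dl + fail_caco2
  status <- ifelse(n_fail == 0L, "passed",
                   ifelse(table$mol_id %in% wl_ids, "rescued", "rejected"))
  flags <- character(nrow(table))
  for (i in which(n_fail > 0L)) {
    flags[i] <- paste(c("OB", "DL", "Caco-2")[c(fail_ob[i], fail_dl[i],
                                                fail_caco2[i])],
                      collapse = ",")
  }
  out <- as.data.frame(table)
  out$status <- status
  out$failed_criteria <- flags
  structure(list(table = out,
                 passed = out$mol_id[status == "passed"],
                 rescued = out$mol_id[status == "rescued"],
                 rejected = out$mol_id[status == "rejected"],
                 criteria = criteria,
                 whitelist = wl_ids),
            class = "screening_result")
}

#' Active compounds of a screening result
#' @param result a \code{screening_result}.
#' @return character vector of mol_ids: passed plus rescued.
#' @export
active_compounds <- function(result) {
  stopifnot(inherits(result, "screening_result"))
  c(result$passed, result$rescued)
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(paste0("ADME screen: %d compounds -> %d passed, ",
                     "%d rescued, %d rejected (active = %d)\n"),
              nrow(x$table), length(x$passed), length(x$rescued),
              length(x$rejected), length(x$passed) + length(x$rescued)))
  invisible(x)
}

#' Drug-likeness floor calibrated from a reference set
#'
#' The conventional 0.18 drug-likeness floor is the mean drug-likeness of
#' a drug-like reference database against its own average profile. This
#' helper recomputes that calibration for an arbitrary reference table,
#' so the floor can be derived from the reference actually in use rather
#' than hard-coded.
#'
#' @param reference_table reference descriptor matrix (rows = molecules).
#' @return list with \code{profile} (the \code{reference_profile}),
#'   \code{dl_values} (per-reference-molecule drug-likeness) and
#'   \code{threshold} (their mean).
#' @export
reference_dl_threshold <- function(reference_table) {
  profile <- compute_reference_profile(reference_table)
  m <- as.matrix(reference_table)
  scaled <- scale_matrix_minmax(m[, profile$descriptor_names, drop = FALSE],
                                profile$scaling_params$min,
                                profile$scaling_params$max)
  dl <- apply(scaled, 1, compute_dl, profile = profile)
  list(profile = profile, dl_values = dl, threshold = mean(dl))
}
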