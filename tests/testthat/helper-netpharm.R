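# Shared fixtures and independent oracles for the test suite.

# write a small compound TSV and return its path
write_tmp_tsv <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# the formula-shaped fixture and its pipeline run are expensive enough
# to build once per test session and share across files
.netpharm_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 7L) {
  key <- paste0("fixture_", seed)
  if (is.null(.netpharm_cache[[key]])) {
    .netpharm_cache[[key]] <- generate_paper_shape_fixture(
      fixture_spec(seed = seed),
      out_dir = file.path(tempdir(), paste0("netpharm_fixture_", seed)))
  }
  .netpharm_cache[[key]]
}

cached_pipeline_run <- function(seed = 7L) {
  key <- paste0("run_", seed)
  if (is.null(.netpharm_cache[[key]])) {
    scn <- cached_fixture(seed)
    out <- file.path(tempdir(), paste0("netpharm_run_", seed))
    .netpharm_cache[[key]] <- list(
      report = run_pipeline(scn$files$config,
                            inputs = list(compounds = scn$files$compounds,
                                          edges = scn$files$edges,
                                          disease = scn$files$disease,
                                          go_gmt = scn$files$go_gmt,
                                          pathway_gmt = scn$files$pathway_gmt),
                            out_dir = out),
      out_dir = out, scenario = scn)
  }
  .netpharm_cache[[key]]
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# enumerate every size-n draw from a universe of N with K marked items
# and count draws with at least k marked members
enumerate_tail <- function(k, K, n, N) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# hand application of the Benjamini-Hochberg step-up formula
stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# random compound table for property tests
random_compound_table <- function(n, seed) {
  set.seed(seed)
  data.frame(mol_id = sprintf("RND%04d", seq_len(n)),
             name = sprintf("random %d", seq_len(n)),
             herbs = sample(c("A", "B", "C"), n, replace = TRUE),
             ob = round(runif(n, 0, 100), 2),
             dl = round(runif(n, 0, 1), 2),
             caco2 = round(runif(n, -2, 2), 2),
             stringsAsFactors = FALSE)
}
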