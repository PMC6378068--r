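test_that("the Tanimoto drug-likeness index matches direct arithmetic", {
  # A.B / (|A|^2 + |B|^2 - A.B) = 4 / (9 + 5 - 4)
  expect_equal(compute_dl(c(1, 2, 2), c(2, 1, 0)), 0.4)
  expect_equal(compute_dl(c(0.3, 0.7, 0.1), c(0.3, 0.7, 0.1)), 1)
  expect_equal(compute_dl(c(0, 0, 0), c(1, 0.5, 0)), 0)
  expect_equal(compute_dl(c(0, 0), c(0, 0)), 0)
  expect_error(compute_dl(c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(compute_dl(c(-1, 2, 2), c(2, 1, 0)), "non-negative")
})

test_that("the drug-likeness index is bounded, symmetric and maximal at identity", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(8)
    b <- runif(8)
    t_ab <- compute_dl(a, b)
    expect_gte(t_ab, 0)
    expect_lte(t_ab, 1)
    expect_equal(t_ab, compute_dl(b, a))
  }
})

test_that("descriptor scaling maps the reference range onto [0, 1]", {
  ref <- rbind(c(d1 = 0, d2 = 10), c(d1 = 4, d2 = 10), c(d1 = 2, d2 = 10))
  profile <- compute_reference_profile(ref)
  expect_warning(s <- scale_descriptors(c(d1 = 0, d2 = 10), profile),
                 "constant")
  expect_equal(unname(s), c(0, 0))
  expect_equal(unname(suppressWarnings(
    scale_descriptors(c(d1 = 4, d2 = 3), profile))), c(1, 0))
  # clamping above the reference maximum
  expect_equal(unname(suppressWarnings(
    scale_descriptors(c(d1 = 9, d2 = 3), profile)))[1], 1)
  expect_error(suppressWarnings(scale_descriptors(c(bogus = 1), profile)),
               "unknown|missing")
})

test_that("the reference profile is the scaled mean with endpoint components at 0.5", {
  ref <- rbind(c(a = 0, b = 0), c(a = 2, b = 8))
  profile <- compute_reference_profile(ref)
  expect_equal(unname(profile$b_vector), c(0.5, 0.5))
  same <- rbind(c(a = 1, b = 3), c(a = 1, b = 3))
  p2 <- compute_reference_profile(same)
  # an all-identical reference collapses to its own (degenerate) profile
  expect_equal(unname(p2$b_vector), c(0, 0))
  expect_error(compute_reference_profile(ref[1, , drop = FALSE]),
               "at least 2")
})

test_that("merging herb lists unions provenance and counts duplicates", {
  h1 <- data.frame(mol_id = c("MOL000098", "M2"), name = c("Quercetin", "x"),
                   herbs = "HMM", ob = c(46.43, 50), dl = c(0.28, 0.3),
                   caco2 = c(0.05, 0.1), stringsAsFactors = FALSE)
  h2 <- data.frame(mol_id = c("MOL000098", "M3"), name = c("Quercetin", "y"),
                   herbs = "HDW", ob = c(46.43, 40), dl = c(0.28, 0.4),
                   caco2 = c(0.05, 0.2), stringsAsFactors = FALSE)
  merged <- merge_herb_lists(list(h1, h2))
  expect_identical(nrow(merged), 3L)
  expect_identical(attr(merged, "n_duplicates"), 1L)
  expect_identical(merged$herbs[merged$mol_id == "MOL000098"], "HDW,HMM")
  # single list is the identity
  expect_identical(nrow(merge_herb_lists(list(h1))), 2L)
  h2_bad <- h2
  h2_bad$ob[1] <- 46.44
  expect_error(merge_herb_lists(list(h1, h2_bad)), "MOL000098")
})

test_that("the three-criterion screen partitions compounds with inclusive floors", {
  tab <- data.frame(
    mol_id = c("pass", "boundary", "rescue", "reject"),
    name = letters[1:4], herbs = "X",
    ob = c(36.16, 30.0, 36.91, 10),
    dl = c(0.25, 0.18, 0.06, 0.01),
    caco2 = c(0.19, 0.0, -0.27, -2),
    stringsAsFactors = FALSE)
  res <- screen_compounds(tab, whitelist = c("rescue"))
  expect_setequal(res$passed, c("pass", "boundary"))
  expect_identical(res$rescued, "rescue")
  expect_identical(res$rejected, "reject")
  flags <- res$table$failed_criteria[res$table$mol_id == "rescue"]
  expect_identical(flags, "DL,Caco-2")
  expect_setequal(active_compounds(res), c("pass", "boundary", "rescue"))
  expect_warning(screen_compounds(tab, whitelist = "ghost"), "ghost")
})

test_that("the representative constituent table screens to 19 passes and 5 rescues", {
  tab <- wpx_representative_compounds()
  rescue_names <- c("Atractylenolide I", "Oleanolic acid",
                    "Astragaloside IV", "Curcumol", "Danshensu")
  whitelist <- tab$mol_id[tab$name %in% rescue_names]
  res <- screen_compounds(tab, screening_criteria(), whitelist)
  expect_length(res$passed, 19L)
  expect_length(res$rescued, 5L)
  expect_length(res$rejected, 0L)
  expect_setequal(res$rescued, whitelist)
  # danshensu fails drug-likeness and permeability but not bioavailability
  dans <- res$table[res$table$name == "Danshensu", ]
  expect_identical(dans$status, "rescued")
  expect_identical(dans$failed_criteria, "DL,Caco-2")
  # oleanolic acid fails only the bioavailability floor (29.02 < 30)
  olea <- res$table[res$table$name == "Oleanolic acid", ]
  expect_identical(olea$failed_criteria, "OB")
})

test_that("screening is monotone in thresholds and whitelist never shrinks the active set", {
  for (seed in 1:5) {
    tab <- random_compound_table(60, seed)
    base <- screen_compounds(tab, screening_criteria(30, 0.18, 0))
    expect_identical(length(base$passed) + length(base$rescued) +
                       length(base$rejected), nrow(tab))
    stricter <- screen_compounds(tab, screening_criteria(40, 0.25, 0.1))
    expect_true(all(stricter$passed %in% base$passed))
    wl <- sample(tab$mol_id, 10)
    rescued <- screen_compounds(tab, screening_criteria(30, 0.18, 0), wl)
    expect_true(all(active_compounds(base) %in% active_compounds(rescued)))
    expect_true(all(rescued$rescued %in% wl))
  }
})

test_that("a reference set calibrates its own drug-likeness floor", {
  ref <- generate_reference_descriptor_set(80, 6, seed = 11)
  cal <- reference_dl_threshold(ref)
  expect_true(all(cal$dl_values >= 0 & cal$dl_values <= 1))
  expect_gt(cal$threshold, 0)
  expect_lt(cal$threshold, 1)
  # the scaled reference mean is maximally drug-like against itself
  expect_equal(compute_dl(cal$profile$b_vector, cal$profile), 1)
})
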