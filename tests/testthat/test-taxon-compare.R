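test_that("taxon grouping is exact, disjoint, and tracks unassigned records", {
  recs <- peptide_records(
    c("a", "b", "c", "d"),
    c("MASSLRAQGT", "KKLLKKLLKK", "ACDEFGHIKL", "LLLLLAAAAA"),
    lineage = list(c("Eukaryota", "Viridiplantae", "Streptophyta"),
                   c("Eukaryota", "Viridiplantae", "Chlorophyta"),
                   c("Eukaryota", "Viridiplantae", "Streptophyta"),
                   character(0)))
  g <- group_by_taxon(recs, c("Streptophyta", "Chlorophyta"))
  expect_equal(g$Streptophyta$id, c("a", "c"))
  expect_equal(g$Chlorophyta$id, "b")
  expect_equal(attr(g, "unassigned"), "d")
  # membership is case-sensitive and exact
  expect_equal(nrow(group_by_taxon(recs, "streptophyta")$streptophyta), 0L)
  # nested taxa at one level overlap -> error naming the record
  expect_error(group_by_taxon(recs, c("Viridiplantae", "Streptophyta")), "a")

  gt <- generate_peptides(preset_spec("two-taxon-demo", n = 200, seed = 4))
  g2 <- group_by_taxon(gt$records, c("Streptophyta", "Chlorophyta"))
  sizes <- table(gt$ground_truth$taxon_of)
  expect_equal(nrow(g2$Streptophyta), unname(sizes["Streptophyta"]))
  expect_equal(nrow(g2$Chlorophyta), unname(sizes["Chlorophyta"]))
})

test_that("identical groups yield p = 1 and label swaps leave p unchanged", {
  recs <- random_records(40, c(12, 20), letters_used = c("A", "S", "L"), seed = 21)
  mat <- count_matrix(recs, 2, mode = "count")
  ids <- colnames(mat)
  # group B duplicates group A's count columns exactly
  dup <- cbind(mat[, 1:20], mat[, 1:20])
  colnames(dup) <- c(ids[1:20], paste0("copy_", ids[1:20]))
  cmp <- mann_whitney_bh(dup, list(A = colnames(dup)[1:20],
                                   B = colnames(dup)[21:40]))
  expect_true(all(abs(cmp$p - 1) < 1e-10))
  expect_false(any(cmp$significant))

  g1 <- list(X = ids[1:20], Y = ids[21:40])
  g2 <- list(Y = ids[21:40], X = ids[1:20])
  c1 <- mann_whitney_bh(mat, g1)
  c2 <- mann_whitney_bh(mat, g2)
  expect_equal(c1$p, c2$p[match(c1$motif, c2$motif)])
  expect_equal(c1$frac_a, c2$frac_b[match(c1$motif, c2$motif)])
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  expect_equal(oracle_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))
    adj <- stats::p.adjust(p, method = "BH")
    expect_equal(adj, oracle_bh(p))
    # monotone in raw-p rank, bounded by 1, never below raw p
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12 & adj <= 1))
  }
})

test_that("adjustment families and small groups behave as documented", {
  recs <- random_records(30, c(12, 20), letters_used = c("A", "S"), seed = 5)
  mat <- count_matrix(recs, 2, mode = "count")
  ids <- colnames(mat)
  cmp <- mann_whitney_bh(mat, list(A = ids[1:15], B = ids[16:30]))
  expect_true(all(cmp$p_adj >= cmp$p - 1e-12))
  expect_true(all(cmp$p_adj <= 1))
  # global family adjusts over more tests, so adjusted p can only grow
  # within each shape family's top-ranked motif
  cmpg <- mann_whitney_bh(mat, list(A = ids[1:15], B = ids[16:30]),
                          family = "global")
  expect_equal(cmp$p, cmpg$p[match(cmp$motif, cmpg$motif)])

  expect_message(out <- mann_whitney_bh(mat, list(A = ids[1], B = ids[2:10])),
                 "fewer than 2")
  expect_equal(nrow(out), 0L)
})

test_that("taxon-specific calls flag exclusives and respect the fraction floor", {
  cmp <- tibble::tibble(
    motif = c("SP", "SS", "AA", "LL"), k = 2L, shape = "0",
    group_a = "A", group_b = "B", n_a = 50L, n_b = 50L,
    frac_a = c(0.30, 0.80, 0.05, 0.00), frac_b = c(0.00, 0.30, 0.01, 0.45),
    U = NA_real_, p = c(1e-6, 1e-4, 0.001, 1e-5),
    p_adj = c(NA, 0.001, 0.004, 1e-4),
    significant = c(NA, TRUE, TRUE, TRUE))
  calls <- taxon_specific_motifs(cmp, min_fraction = 0.1)
  expect_setequal(calls$motif, c("SP", "SS", "LL"))
  expect_equal(calls$call[calls$motif == "SP"], "exclusive_a")
  expect_equal(calls$call[calls$motif == "LL"], "exclusive_b")
  expect_equal(calls$call[calls$motif == "SS"], "enriched_a")
  # AA is significant but below the floor in both groups
  expect_false("AA" %in% calls$motif)
})

test_that("a strongly differential planted motif is detected in one replicate", {
  spec <- preset_spec("two-taxon-demo", n = 240, seed = 33)
  gen <- generate_peptides(spec)
  groups <- group_by_taxon(gen$records, c("Streptophyta", "Chlorophyta"))
  mat <- count_matrix(gen$records, 2, mode = "count")
  cmp <- mann_whitney_bh(mat, groups)
  row <- cmp[cmp$motif == "S_S", ]
  expect_true(row$significant)
  expect_gt(row$frac_a, row$frac_b)
  calls <- taxon_specific_motifs(cmp, min_fraction = 0.1)
  expect_true("S_S" %in% calls$motif)
  sp <- calls[calls$motif == "SP", ]
  expect_equal(sp$call, "exclusive_a")
})
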