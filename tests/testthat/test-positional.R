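test_that("scaled start positions follow 100*(s-0.5)/L", {
  rec <- peptide_records("a", paste0("MA", strrep("G", 48)))
  expect_equal(scaled_positions(rec, "MA"), 1.0)

  # last possible bigram start in a length-50 sequence: 1-based 49
  rec2 <- peptide_records("b", paste0(strrep("G", 48), "MA"))
  expect_equal(scaled_positions(rec2, "MA"), 97.0)

  # no occurrences: empty vector, not an error
  expect_length(scaled_positions(rec, "KK"), 0L)

  pos <- scaled_positions(peptide_records("c", "SASAS"), "S_S")
  expect_equal(pos, 100 * c(0.5, 2.5) / 5)
  expect_true(all(pos > 0 & pos < 100))
})

test_that("profiles conserve unit mass and are invariant to dataset duplication", {
  recs <- random_records(40, c(15, 40), letters_used = c("A", "S", "L"), seed = 3)
  prof <- positional_profile(recs, "SS")
  expect_equal(sum(prof$mass), 1)
  expect_equal(length(prof$mass), 20L)

  doubled <- peptide_records(c(recs$id, paste0(recs$id, "_2")),
                             rep(recs$sequence, 2))
  prof2 <- positional_profile(doubled, "SS")
  expect_equal(prof2$mass, prof$mass)
  expect_equal(prof2$n, 2L * prof$n)

  # degenerate: zero occurrences gives an all-zero profile with n = 0
  empty <- positional_profile(recs, "WW")
  expect_equal(empty$n, 0L)
  expect_equal(sum(empty$mass), 0)
})

test_that("uniformly planted starts pass a Kolmogorov-Smirnov uniformity check", {
  # long sequences make the scaled support effectively (0, 100); the planted
  # motif's letters are absent from the background so every occurrence is a
  # planted one
  spec <- generator_spec(2000, "cTP", c(400L, 600L),
                         background = restricted_background(
                           c("A", "S", "G", "T", "P", "L")),
                         planted = tibble::tibble(motif = "KR", prob = 1,
                                                  position = "uniform"),
                         seed = 12)
  recs <- generate_peptides(spec)$records
  pos <- scaled_positions(recs, "KR")
  expect_gte(length(pos), 2000L)
  ks <- suppressWarnings(stats::ks.test(pos / 100, "punif"))
  crit <- 1.628 / sqrt(length(pos))  # alpha = 0.01 asymptotic critical value
  expect_lt(unname(ks$statistic), crit)
})

test_that("region classification follows the thirds rule deterministically", {
  mkprof <- function(mass, n = 100L) {
    breaks <- seq(0, 100, 5)
    structure(list(motif = "XX", breaks = breaks,
                   mids = (breaks[-1] + breaks[-21]) / 2,
                   mass = mass, n = n), class = "positional_profile")
  }
  m <- rep(0, 20)
  m[1] <- 1
  expect_equal(classify_region(mkprof(m))$region, "N-terminus")
  expect_equal(classify_region(mkprof(rep(1 / 20, 20)))$region, "whole")
  m <- rep(0, 20); m[4:7] <- 0.25
  expect_equal(classify_region(mkprof(m))$region, "first-part")
  m <- rep(0, 20); m[8:14] <- 1 / 7
  expect_equal(classify_region(mkprof(m))$region, "middle")
  m <- c(rep(0.5 / 7, 7), rep(0.5 / 7, 7), rep(0, 6))
  expect_equal(classify_region(mkprof(m))$region, "C-depleted")
  m <- c(rep(0.2 / 7, 7), rep(0.2 / 7, 7), rep(0.6 / 6, 6))
  expect_equal(classify_region(mkprof(m))$region, "C-enriched")
  # low support forces "whole" with a flag
  call <- classify_region(mkprof(c(1, rep(0, 19)), n = 5L))
  expect_equal(call$region, "whole")
  expect_true(call$low_support)
  # pure function of the profile vector
  expect_identical(classify_region(mkprof(rep(1 / 20, 20))),
                   classify_region(mkprof(rep(1 / 20, 20))))
})

test_that("planted positional structure is recovered end to end", {
  # N-terminal planting: MA as the first two residues of 80% of sequences
  spec <- preset_spec("cTP-like", n = 400, seed = 8)
  gen <- generate_peptides(spec)
  recs <- gen$records
  prof <- positional_profile(recs, "MA")
  expect_gte(sum(prof$mass[1:4]), 0.75)
  expect_equal(classify_region(prof)$region, "N-terminus")
  # the prefix test can only exceed the realized intact planting fraction
  ins <- gen$ground_truth$insertions
  realized <- sum(ins$motif == "MA" & ins$intact) / nrow(recs)
  expect_gte(prefix_fraction(recs, "MA"), realized)
  expect_gte(prefix_fraction(recs, "MA"), 0.72)

  # mid-region planting: LL in signal-peptide-like sequences sits in the
  # middle third
  sp <- generate_peptides(preset_spec("SP-like", n = 400, seed = 8))$records
  call <- classify_region(positional_profile(sp, "LL"))
  expect_equal(call$region, "middle")
})
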