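test_that("presequence extraction takes the 1-based N-terminal prefix", {
  rec <- peptide_records("p1", "MASSLRAQGTK")
  out <- extract_presequence(rec, 10)
  expect_equal(out$sequence, "MASSLRAQGT")
  expect_equal(out$id, "p1")

  # whole-sequence edge case
  rec2 <- peptide_records("p2", "MK")
  expect_equal(extract_presequence(rec2, 2)$sequence, "MK")

  expect_error(extract_presequence(rec, 0), "out of range")
  expect_error(extract_presequence(rec, 12), "out of range")
})

test_that("filtering applies nonstandard -> short -> long -> duplicate, once each", {
  recs <- peptide_records(c("a", "b", "c"),
                          c("ACDEFGHIKL", "ACDEFGHIK", "ACDEFGHIXL"))
  fl <- filter_dataset(recs)
  expect_equal(fl$records$sequence, "ACDEFGHIKL")
  expect_equal(unclass(fl$report)[c("n_input", "n_removed_nonstandard",
                                    "n_removed_short", "n_removed_long",
                                    "n_removed_duplicate", "n_output")],
               list(n_input = 3L, n_removed_nonstandard = 1L,
                    n_removed_short = 1L, n_removed_long = 0L,
                    n_removed_duplicate = 0L, n_output = 1L))

  dup <- peptide_records(c("x", "y"), c("KKLLKKLLKK", "KKLLKKLLKK"))
  fd <- filter_dataset(dup)
  expect_equal(fd$records$id, "x")   # first occurrence kept
  expect_equal(fd$report$n_removed_duplicate, 1L)

  # max_len applies to antimicrobial sets
  amp <- peptide_records("z", strrep("K", 101), seq_type = "AMP")
  expect_equal(filter_dataset(amp, max_len = 100)$report$n_removed_long, 1L)

  # empty input: zeroed report, not an error
  empty <- filter_dataset(peptide_records(character(0), character(0))[0, ])
  expect_equal(empty$report$n_input, 0L)
  expect_equal(empty$report$n_output, 0L)
})

test_that("filtering is idempotent, order-preserving, and its ledger sums", {
  set.seed(31)
  for (rep in 1:5) {
    recs <- random_records(80, c(5, 25))
    # sprinkle violations
    i <- sample(80, 12)
    substr(recs$sequence[i[1:4]], 1, 1) <- "X"
    recs$sequence[i[5:8]] <- recs$sequence[sample(setdiff(seq_len(80), i), 4)]
    fl <- filter_dataset(recs)
    rep1 <- fl$report
    expect_equal(rep1$n_input,
                 rep1$n_output + rep1$n_removed_nonstandard +
                   rep1$n_removed_short + rep1$n_removed_long +
                   rep1$n_removed_duplicate)
    # idempotent
    fl2 <- filter_dataset(fl$records)
    expect_identical(fl2$records, fl$records)
    expect_equal(fl2$report$n_output, fl2$report$n_input)
    # survivor order preserves input order
    expect_identical(fl$records$id, recs$id[recs$id %in% fl$records$id])
  }
})

test_that("FASTA + metadata reading joins, rejects, and extracts presequences", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">p1 some description", "MASSLRAQ", "GTKWYV",
               ">p2", "KKLLKKLLKK",
               ">orphan", "ACDEFGHIKL"), fa)
  writeLines(c("id\tseq_type\tlineage\tcleavage_pos",
               "p1\tcTP\tEukaryota;Viridiplantae;Streptophyta\t10",
               "p2\tAMP\t\t"), tsv)
  expect_message(recs <- read_peptides(fa, tsv), "absent from metadata")
  expect_equal(nrow(recs), 2L)
  # presequence extracted before filtering using the cleavage annotation
  expect_equal(recs$sequence[recs$id == "p1"], "MASSLRAQGT")
  expect_equal(recs$lineage[[1]], c("Eukaryota", "Viridiplantae", "Streptophyta"))
  expect_equal(recs$lineage[[2]], character(0))
  rej <- attr(recs, "rejections")
  expect_equal(rej$id, "orphan")

  # out-of-range cleavage position rejects the record with a reason
  writeLines(c("id\tseq_type\tlineage\tcleavage_pos",
               "p1\tcTP\tx\t99",
               "p2\tAMP\t\t"), tsv)
  expect_message(recs2 <- read_peptides(fa, tsv), "out-of-range")
  expect_equal(recs2$id, "p2")
  expect_true("p1" %in% attr(recs2, "rejections")$id)

  # duplicate FASTA ids are an error naming the id
  writeLines(c(">p1", "MASS", ">p1", "KKLL"), fa)
  expect_error(read_peptides(fa, tsv), "p1")
})

test_that("peptide records round-trip through write_peptides/read_peptides", {
  recs <- generate_peptides(preset_spec("two-taxon-demo", n = 30, seed = 2))$records
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_peptides(recs, fa, tsv)
  back <- read_peptides(fa, tsv)
  attr(back, "rejections") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(recs))
})
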