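test_that("shape enumeration matches brute force and the per-size gap rules", {
  expect_equal(enumerate_shapes(2), list(0L, 1L, 2L, 3L))
  expect_equal(enumerate_shapes(3), oracle_shapes(3, 3))
  expect_equal(enumerate_shapes(4), oracle_shapes(4, 2))
  # size 5: contiguous plus exactly one single-residue gap
  s5 <- enumerate_shapes(5)
  expect_length(s5, 5)
  expect_true(all(vapply(s5, function(g) sum(g) <= 1 && all(g %in% 0:1), logical(1))))
  expect_equal(s5[[1]], rep(0L, 4))

  counts <- vapply(2:5, function(k) length(enumerate_shapes(k)), integer(1))
  expect_equal(counts, c(4L, 16L, 27L, 5L))
  expect_equal(sum(counts), 52L)

  all_shapes <- unlist(lapply(2:5, function(k) {
    vapply(enumerate_shapes(k), function(g) k + sum(g), integer(1))
  }))
  expect_true(all(all_shapes <= 10))
  # the span-10 tetragram shape (2,2,2) is included
  expect_true(any(vapply(enumerate_shapes(4), identical, logical(1), y = c(2L, 2L, 2L))))
  expect_error(enumerate_shapes(6), "2, 3, 4, 5")
  expect_error(enumerate_shapes(1), "2, 3, 4, 5")
})

test_that("motif parsing and formatting round-trip and reject malformed input", {
  p <- parse_motif("S_S")
  expect_equal(p$classes, list("S", "S"))
  expect_equal(p$gaps, 1L)
  expect_equal(format_motif(p), "S_S")

  # underscore count encodes the number of unspecified residues
  expect_equal(parse_motif("L___L")$gaps, 3L)
  expect_equal(parse_motif("S__S")$span, 4L)

  br <- parse_motif("[AVIL]__[AVIL][AVIL]")
  expect_equal(br$classes[[1]], c("A", "I", "L", "V"))
  expect_equal(br$gaps, c(2L, 0L))
  expect_equal(parse_motif(format_motif(br)), br)

  for (m in c("SS", "K__K", "A_R_L", "TLLLT", "LL_LL", "[ST]_[ST]")) {
    expect_equal(format_motif(parse_motif(m)), m)
  }

  expect_error(parse_motif("_AB"), "start")
  expect_error(parse_motif("AB_"), "end")
  expect_error(parse_motif("A[]B"), "empty")
  expect_error(parse_motif("ABCDEF"), "between 2 and 5")
  expect_error(parse_motif("A____B"), "shape")   # bigram gap beyond 3
  expect_error(parse_motif("AB[CD"), "unclosed")
})

test_that("occurrence finding reports all overlapping starts", {
  r <- find_occurrences("MASSS", "S_S")
  expect_equal(r$count, 1L)
  expect_equal(r$starts, 3L)

  r <- find_occurrences("LLLL", "LL")
  expect_equal(r$starts, 1:3)

  # motif longer than the sequence: zero occurrences, not an error
  expect_equal(find_occurrences("MK", "K___K")$count, 0L)
  # class sets match any member
  expect_equal(find_occurrences("MALV", "[AVIL]_[AVIL]")$starts, 2L)
})

test_that("occurrence finding agrees with the regex-lookahead oracle", {
  set.seed(71)
  letters_used <- c("A", "S", "L", "K", "R", "M", "P", "T")
  for (case in seq_len(500)) {
    L <- sample(5:30, 1)
    s <- paste(sample(letters_used, L, replace = TRUE), collapse = "")
    pat <- random_pattern(letters_used)
    expect_identical(find_occurrences(s, pat)$starts,
                     oracle_starts(s, pat$classes, pat$gaps))
  }
})

test_that("count matrices are lazy, deterministic, and correct on plants", {
  r1 <- peptide_records("s1", "SS")
  m <- count_matrix(r1, 2)
  expect_equal(rownames(m), "SS")
  expect_equal(as.numeric(m["SS", ]), 1)

  r3 <- peptide_records(c("a", "b", "c"), c("SSA", "ASA", "AAA"))
  m3 <- count_matrix(r3, 2)
  expect_equal(sum(m3["SS", ]), 1)

  # no motif row is ever all-zero (nothing materialized beyond observations)
  expect_true(all(Matrix::rowSums(m3) > 0))

  # planted presence: LR written into exactly 37 of 100 L/R-free backgrounds
  set.seed(5)
  base <- random_records(100, c(12, 20), letters_used = c("A", "S", "T", "G"))
  idx <- sort(sample(100, 37))
  for (i in idx) {
    s <- base$sequence[i]
    pos <- sample(nchar(s) - 1L, 1)
    substr(base$sequence[i], pos, pos + 1L) <- "LR"
  }
  pm <- count_matrix(base, 2, mode = "presence")
  expect_equal(sum(pm["LR", ]), 37)

  # count mode dominates presence mode elementwise
  cm <- count_matrix(base, 2, mode = "count")
  expect_true(all(cm >= pm))
  expect_identical(rownames(cm), rownames(pm))

  # identical input -> identical matrix (row order is deterministic)
  pm2 <- count_matrix(base, 2, mode = "presence")
  expect_identical(as.matrix(pm), as.matrix(pm2))

  # empty input
  m0 <- count_matrix(peptide_records(character(0), character(0))[0, ], 2)
  expect_equal(dim(m0), c(0L, 0L))
})

test_that("sub-pattern presence is monotone: trigram <= each embedded bigram", {
  set.seed(42)
  recs <- random_records(60, c(10, 25), letters_used = c("A", "S", "L", "R"))
  pres <- count_matrix(recs, 2:3, mode = "presence")
  tot <- Matrix::rowSums(pres)
  info <- motif_info(rownames(pres))
  tri <- info[info$k == 3, ]
  for (i in seq_len(nrow(tri))) {
    p <- parse_motif(tri$motif[i])
    g <- p$gaps
    left <- format_motif(motif_pattern(p$classes[1:2], g[1]))
    right <- format_motif(motif_pattern(p$classes[2:3], g[2]))
    expect_lte(tot[tri$motif[i]], min(tot[left], tot[right]))
  }
})
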