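# Independent oracles used across the suite. These deliberately avoid the
# package's own matching/enumeration code paths.

# Regex-with-lookahead oracle for overlapping gapped-motif occurrences.
# classes: list of character vectors; gaps: integer vector.
oracle_starts <- function(sequence, classes, gaps) {
  parts <- vapply(seq_along(classes), function(i) {
    cl <- classes[[i]]
    cls <- if (length(cl) == 1L) cl else paste0("[", paste(cl, collapse = ""), "]")
    gap <- if (i < length(classes) && gaps[i] > 0) paste0(".{", gaps[i], "}") else ""
    paste0(cls, gap)
  }, character(1))
  re <- paste0("(?=", paste(parts, collapse = ""), ")")
  m <- gregexpr(re, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Brute-force shape enumeration: all gap tuples under a per-slot bound,
# keeping those with span <= 10. Used to cross-check enumerate_shapes().
oracle_shapes <- function(k, per_slot) {
  grid <- expand.grid(rep(list(0:per_slot), k - 1))
  keep <- k + rowSums(grid) <= 10
  grid <- grid[keep, , drop = FALSE]
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# Hand-written Benjamini-Hochberg step-up: adj_i = min_{j >= rank(i)} m*p_(j)/j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Random peptide record table over a restricted letter set.
random_records <- function(n, len_range = c(10, 30), letters_used = NULL,
                           seed = NULL, seq_type = "cTP") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(letters_used)) {
    letters_used <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  }
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(letters_used, L, replace = TRUE), collapse = "")
  }, character(1))
  peptide_records(sprintf("seq%04d", seq_len(n)), seqs, seq_type)
}

# A uniform background restricted to a letter subset (others at probability 0).
restricted_background <- function(letters_used) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  p <- setNames(rep(0, 20), aa)
  p[letters_used] <- 1 / length(letters_used)
  p
}

# Random allowed motif pattern over a letter set: picks a size, one of its
# shapes, and random singleton classes.
random_pattern <- function(letters_used) {
  k <- sample(2:5, 1)
  shapes <- enumerate_shapes(k)
  gaps <- shapes[[sample(length(shapes), 1)]]
  motif_pattern(as.list(sample(letters_used, k, replace = TRUE)), gaps)
}
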