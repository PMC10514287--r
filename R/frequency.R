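#' Presence-frequency table for a motif count matrix
#'
#' The frequency of a motif is the fraction of sequences in the set that
#' contain it at least once. Works on matrices from [count_matrix()] in
#' either mode (entries are tested against zero).
#'
#' @param mat motif-by-sequence sparse matrix.
#' @param n_sequences number of sequences the fractions refer to; defaults to
#'   the number of matrix columns.
#' @param seq_type optional label stored in the table.
#' @param alphabet_name label of the alphabet used (default `"full"`).
#' @return tibble with columns `motif`, `k`, `shape`, `n_present`, `n`,
#'   `fraction`, sorted by decreasing fraction, ties broken by the canonical
#'   motif string.
#' @export
frequency_table <- function(mat, n_sequences = ncol(mat), seq_type = NA_character_,
                            alphabet_name = "full") {
  if (is.null(n_sequences) || n_sequences == 0L) {
    stop("n_sequences must be positive", call. = FALSE)
  }
  present <- Matrix::rowSums(mat != 0)
  info <- motif_info(rownames(mat))
  tab <- tibble::tibble(
    motif = rownames(mat),
    k = info$k,
    shape = info$shape,
    n_present = as.integer(present),
    n = as.integer(n_sequences),
    fraction = as.numeric(present) / n_sequences,
    seq_type = seq_type,
    alphabet = alphabet_name
  )
  tab[order(-tab$fraction, tab$motif), , drop = FALSE]
}

#' Default per-size frequency cutoffs for reporting
#'
#' Presentation-layer defaults only: full tables are always retained and
#' thresholds never affect stored results.
#'
#' @return named numeric vector, names are motif sizes.
#' @export
default_thresholds <- function() {
  c(`2` = 0.25, `3` = 0.10, `4` = 0.05, `5` = 0.05)
}

#' Keep the motifs above a per-size frequency cutoff
#'
#' @param table a frequency table from [frequency_table()].
#' @param thresholds named numeric vector of fraction cutoffs keyed by motif
#'   size (as character); sizes without an entry default to 0.
#' @return the filtered table (same ordering).
#' @export
top_motifs <- function(table, thresholds = default_thresholds()) {
  cut <- thresholds[as.character(table$k)]
  cut[is.na(cut)] <- 0
  table[table$fraction >= cut, , drop = FALSE]
}

#' Within-sequence repeat statistics
#'
#' Considers only motifs found at least twice in at least one sequence, and
#' reports, per motif, the maximum number of occurrences observed in any
#' single sequence (overlaps allowed) and the fractions of sequences with at
#' least two and at least three occurrences.
#'
#' @param records peptide record table (filtered).
#' @param k_range motif sizes, subset of 2:5.
#' @param alphabet optional `reduced_alphabet`.
#' @return tibble with columns `motif`, `k`, `shape`, `max_repeats`,
#'   `frac_ge2`, `frac_ge3`, sorted by decreasing `max_repeats`.
#' @export
repeat_analysis <- function(records, k_range = 2:5, alphabet = NULL) {
  mat <- count_matrix(records, k_range = k_range, mode = "count",
                      alphabet = alphabet)
  n <- ncol(mat)
  if (nrow(mat) == 0L) {
    return(tibble::tibble(motif = character(0), k = integer(0),
                          shape = character(0), max_repeats = integer(0),
                          frac_ge2 = numeric(0), frac_ge3 = numeric(0)))
  }
  max_rep <- apply_rows_max(mat)
  keep <- max_rep >= 2
  mat <- mat[keep, , drop = FALSE]
  max_rep <- max_rep[keep]
  info <- motif_info(rownames(mat))
  tab <- tibble::tibble(
    motif = rownames(mat),
    k = info$k,
    shape = info$shape,
    max_repeats = as.integer(max_rep),
    frac_ge2 = as.numeric(Matrix::rowSums(mat >= 2)) / n,
    frac_ge3 = as.numeric(Matrix::rowSums(mat >= 3)) / n
  )
  tab[order(-tab$max_repeats, tab$motif), , drop = FALSE]
}

# Row maxima of a non-negative sparse matrix without densifying.
apply_rows_max <- function(mat) {
  tri <- methods::as(mat, "TsparseMatrix")
  out <- numeric(nrow(mat))
  if (length(tri@x)) {
    dt <- data.table::data.table(i = tri@i + 1L, x = tri@x)
    mx <- dt[, list(m = max(x)), by = "i"]
    out[mx$i] <- mx$m
  }
  out
}
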