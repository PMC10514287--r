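#' Partition records by taxon membership
#'
#' Membership is a case-sensitive exact match of the taxon name against the
#' elements of each record's lineage. The groups used in one comparison must
#' be disjoint (nested taxa cannot be compared against each other directly).
#'
#' @param records peptide record table.
#' @param taxon_names character vector of taxon names.
#' @return named list of record subsets, one per taxon, with an
#'   `unassigned` attribute holding the ids matching none of them.
#' @export
group_by_taxon <- function(records, taxon_names) {
  membership <- vapply(taxon_names, function(tx) {
    vapply(records$lineage, function(lin) tx %in% lin, logical(1))
  }, logical(nrow(records)))
  membership <- matrix(membership, nrow = nrow(records),
                       dimnames = list(NULL, taxon_names))
  hits <- rowSums(membership)
  if (any(hits > 1L)) {
    bad <- records$id[hits > 1L][1]
    stop("groups overlap at this comparison level: record ", bad,
         " belongs to more than one of ", paste(taxon_names, collapse = ", "),
         call. = FALSE)
  }
  groups <- lapply(taxon_names, function(tx) {
    records[membership[, tx], , drop = FALSE]
  })
  names(groups) <- taxon_names
  attr(groups, "unassigned") <- records$id[hits == 0L]
  groups
}

#' Mann-Whitney U tests with Benjamini-Hochberg correction across motifs
#'
#' For every motif observed in either group, compares the per-sequence
#' occurrence counts (zeros included for sequences lacking the motif) between
#' the two groups with a two-sided Mann-Whitney U test: the exact null
#' distribution when both groups have at most 8 sequences, the tie-corrected
#' normal approximation otherwise. P-values are Benjamini-Hochberg adjusted
#' within a family of tests: by default all motifs sharing a size and gap
#' shape within this comparison.
#'
#' @param mat motif-by-sequence matrix from [count_matrix()] (mode
#'   `"count"` for the default count observable; a presence-mode matrix
#'   yields the presence observable).
#' @param groups named list of two character vectors of sequence ids (matrix
#'   column names), or the output of [group_by_taxon()] restricted to two
#'   taxa.
#' @param alpha significance level applied to the adjusted p-values.
#' @param family `"k_shape"` (default): adjust within each motif size and
#'   gap-shape; `"k"`: within each size; `"global"`: across all motifs.
#' @return tibble with one row per motif: `motif`, `k`, `shape`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `frac_a`, `frac_b` (presence fractions),
#'   `U`, `p`, `p_adj`, `significant`. Rows are ordered by size, shape and
#'   motif string (deterministic). Comparisons where a group has fewer than
#'   2 sequences return an empty table with a message.
#' @export
mann_whitney_bh <- function(mat, groups, alpha = 0.05,
                            family = c("k_shape", "k", "global")) {
  family <- match.arg(family)
  if (length(groups) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- c("A", "B")
  }
  ids <- lapply(groups, function(g) {
    if (is.data.frame(g)) g$id else as.character(g)
  })
  missing <- setdiff(unlist(ids), colnames(mat))
  if (length(missing)) {
    stop("ids not present in the count matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  n_a <- length(ids[[1]])
  n_b <- length(ids[[2]])
  empty <- tibble::tibble(motif = character(0), k = integer(0),
                          shape = character(0), group_a = character(0),
                          group_b = character(0), n_a = integer(0),
                          n_b = integer(0), frac_a = numeric(0),
                          frac_b = numeric(0), U = numeric(0), p = numeric(0),
                          p_adj = numeric(0), significant = logical(0))
  if (n_a < 2L || n_b < 2L) {
    message("comparison skipped: group '",
            names(groups)[which.min(c(n_a, n_b))],
            "' has fewer than 2 sequences")
    return(empty)
  }
  sub <- mat[, c(ids[[1]], ids[[2]]), drop = FALSE]
  keep <- Matrix::rowSums(sub != 0) > 0
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) == 0L) return(empty)

  use_exact <- max(n_a, n_b) <= 8L
  ga <- seq_len(n_a)
  gb <- n_a + seq_len(n_b)
  motifs <- rownames(sub)
  p <- numeric(length(motifs))
  U <- numeric(length(motifs))
  frac_a <- numeric(length(motifs))
  frac_b <- numeric(length(motifs))
  block <- 2000L
  for (lo in seq(1L, length(motifs), by = block)) {
    hi <- min(lo + block - 1L, length(motifs))
    dense <- as.matrix(sub[lo:hi, , drop = FALSE])
    for (r in seq_len(nrow(dense))) {
      xa <- dense[r, ga]
      xb <- dense[r, gb]
      wt <- suppressWarnings(
        stats::wilcox.test(xa, xb, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
      )
      i <- lo + r - 1L
      p[i] <- wt$p.value
      U[i] <- unname(wt$statistic)
      frac_a[i] <- mean(xa > 0)
      frac_b[i] <- mean(xb > 0)
    }
  }
  info <- motif_info(motifs)
  fam <- switch(family,
                k_shape = paste(info$k, info$shape, sep = "|"),
                k = as.character(info$k),
                global = rep("all", length(motifs)))
  p_adj <- numeric(length(p))
  for (f in unique(fam)) {
    idx <- fam == f
    p_adj[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out <- tibble::tibble(
    motif = motifs, k = info$k, shape = info$shape,
    group_a = names(groups)[1], group_b = names(groups)[2],
    n_a = n_a, n_b = n_b, frac_a = frac_a, frac_b = frac_b,
    U = U, p = p, p_adj = p_adj, significant = p_adj <= alpha
  )
  out[order(out$k, out$shape, out$motif), , drop = FALSE]
}

#' Taxon-specific motif calls
#'
#' Flags motifs that are significantly different between the two groups and
#' reach a minimum presence fraction in the enriched group, and separately
#' flags "exclusive" motifs (presence fraction exactly 0 in one group and
#' positive in the other), which bypass the test. The same minimum-fraction
#' requirement applies to the enriched side of exclusive calls.
#'
#' @param comparisons output of [mann_whitney_bh()].
#' @param min_fraction minimum presence fraction in the enriched group.
#' @return the filtered comparison table with extra columns `exclusive`
#'   (logical) and `call` (one of `enriched_a`, `enriched_b`, `exclusive_a`,
#'   `exclusive_b`).
#' @export
taxon_specific_motifs <- function(comparisons, min_fraction = 0.1) {
  excl_a <- comparisons$frac_b == 0 & comparisons$frac_a > 0
  excl_b <- comparisons$frac_a == 0 & comparisons$frac_b > 0
  exclusive <- excl_a | excl_b
  enriched <- pmax(comparisons$frac_a, comparisons$frac_b)
  keep <- (exclusive | comparisons$significant) & enriched >= min_fraction
  out <- comparisons[keep, , drop = FALSE]
  excl_a <- excl_a[keep]
  excl_b <- excl_b[keep]
  out$exclusive <- excl_a | excl_b
  out$call <- ifelse(excl_a, "exclusive_a",
                     ifelse(excl_b, "exclusive_b",
                            ifelse(out$frac_a >= out$frac_b,
                                   "enriched_a", "enriched_b")))
  out
}
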