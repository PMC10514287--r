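#' Assemble a peptide record table
#'
#' The central container of the package: one row per peptide, with an
#' identifier, the residue string, the sequence type (chloroplast or
#' mitochondrial transit peptide, signal peptide, or antimicrobial peptide)
#' and the taxonomic lineage (root-to-leaf, possibly empty).
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of residue strings (uppercased on entry).
#' @param seq_type one of `"cTP"`, `"mTP"`, `"SP"`, `"AMP"` (recycled).
#' @param lineage list of character vectors (one per record), a single
#'   character vector recycled to all records, or `NULL` for empty lineages.
#' @return a tibble with columns `id`, `sequence`, `seq_type`, `lineage`
#'   (list column).
#' @export
peptide_records <- function(id, sequence, seq_type = "cTP", lineage = NULL) {
  n <- length(sequence)
  id <- as.character(id)
  if (length(id) != n) stop("id and sequence lengths differ", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1], call. = FALSE)
  }
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence))) stop("sequences must be non-empty", call. = FALSE)
  seq_type <- rep_len(as.character(seq_type), n)
  if (!all(seq_type %in% SEQ_TYPES)) {
    stop("seq_type must be one of ", paste(SEQ_TYPES, collapse = ", "), call. = FALSE)
  }
  if (is.null(lineage)) {
    lineage <- rep(list(character(0)), n)
  } else if (!is.list(lineage)) {
    lineage <- rep(list(as.character(lineage)), n)
  }
  stopifnot(length(lineage) == n)
  tibble::tibble(id = id, sequence = sequence, seq_type = seq_type,
                 lineage = lineage)
}

#' Extract a presequence by its annotated cleavage position
#'
#' Cuts the N-terminal part of a full protein: residues 1..cleavage_pos
#' (1-based, inclusive) become the presequence; id, type and lineage are
#' preserved.
#'
#' @param record a one-row peptide record table.
#' @param cleavage_pos 1-based index of the last presequence residue.
#' @return the record with `sequence` truncated.
#' @export
extract_presequence <- function(record, cleavage_pos) {
  stopifnot(nrow(record) == 1L)
  len <- nchar(record$sequence)
  if (length(cleavage_pos) != 1L || is.na(cleavage_pos) ||
      cleavage_pos < 1L || cleavage_pos > len) {
    stop("cleavage position ", cleavage_pos, " out of range 1..", len,
         " for record ", record$id, call. = FALSE)
  }
  record$sequence <- substr(record$sequence, 1L, cleavage_pos)
  record
}

.nonstandard_re <- function() paste0("[^", paste(AA_STANDARD, collapse = ""), "]")

#' Filter a peptide set and account for every removal
#'
#' Applies, in order: removal of sequences with nonstandard or ambiguous
#' residues (anything outside the 20 standard letters, including B, J, O, U,
#' X, Z), removal of sequences shorter than `min_len`, removal of sequences
#' longer than `max_len` (if set; used for antimicrobial peptides, capped at
#' 100), and removal of exact duplicate residue strings (first occurrence
#' kept). A sequence failing several rules is counted once, under the first.
#' Survivor order follows input order.
#'
#' @param records peptide record table.
#' @param min_len minimum length kept (default 10).
#' @param max_len optional maximum length kept (`NULL` = no bound).
#' @return list with `records` (the survivors) and `report`, a
#'   `filter_report` whose counts sum exactly to the input size.
#' @export
filter_dataset <- function(records, min_len = 10L, max_len = NULL) {
  n_input <- nrow(records)
  ok <- !grepl(.nonstandard_re(), records$sequence)
  n_nonstandard <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  len <- nchar(records$sequence)
  ok <- len >= min_len
  n_short <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  n_long <- 0L
  if (!is.null(max_len)) {
    ok <- nchar(records$sequence) <= max_len
    n_long <- sum(!ok)
    records <- records[ok, , drop = FALSE]
  }

  ok <- !duplicated(records$sequence)
  n_dup <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  report <- structure(list(
    n_input = n_input,
    n_removed_nonstandard = n_nonstandard,
    n_removed_short = n_short,
    n_removed_long = n_long,
    n_removed_duplicate = n_dup,
    n_output = nrow(records)
  ), class = "filter_report")
  list(records = records, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter report: ", x$n_input, " in -> ", x$n_output, " out (",
      x$n_removed_nonstandard, " nonstandard, ", x$n_removed_short, " short, ",
      x$n_removed_long, " long, ", x$n_removed_duplicate, " duplicate)\n",
      sep = "")
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report`.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read peptides from FASTA plus a metadata table
#'
#' The metadata is tab-separated with a header row and columns `id`,
#' `seq_type`, `lineage` (semicolon-delimited, root to leaf; may be empty)
#' and optionally `cleavage_pos`. When `cleavage_pos` is present and
#' non-missing, the presequence is extracted from the full protein before
#' any filtering. FASTA records whose id is absent from the metadata, or
#' whose cleavage position is out of range, are rejected with a logged
#' reason (available as `attr(x, "rejections")`).
#'
#' @param fasta_path FASTA file of peptide/protein sequences (wrapped lines
#'   allowed).
#' @param metadata_path TSV metadata file.
#' @return a peptide record table; rejected ids and reasons in the
#'   `rejections` attribute.
#' @export
read_peptides <- function(fasta_path, metadata_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate id within FASTA: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            colClasses = "character")
  required <- c("id", "seq_type", "lineage")
  if (!all(required %in% names(meta))) {
    stop("metadata must have columns id, seq_type, lineage", call. = FALSE)
  }
  rejections <- tibble::tibble(id = character(0), reason = character(0))
  keep <- ids %in% meta$id
  if (any(!keep)) {
    rejections <- rbind(rejections, tibble::tibble(
      id = ids[!keep], reason = "id absent from metadata"))
    message(sum(!keep), " FASTA record(s) absent from metadata were rejected")
  }
  seqs <- as.character(aa)[keep]
  ids <- ids[keep]
  m <- meta[match(ids, meta$id), , drop = FALSE]
  lineage <- lapply(strsplit(m$lineage, ";", fixed = TRUE), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  lineage[is.na(m$lineage)] <- list(character(0))
  records <- peptide_records(ids, seqs, m$seq_type, lineage)

  if ("cleavage_pos" %in% names(m)) {
    cp <- suppressWarnings(as.integer(m$cleavage_pos))
    has_cp <- !is.na(cp)
    bad <- has_cp & (cp < 1L | cp > nchar(records$sequence))
    if (any(bad)) {
      rejections <- rbind(rejections, tibble::tibble(
        id = records$id[bad], reason = "cleavage position out of range"))
      message(sum(bad), " record(s) with out-of-range cleavage positions were rejected")
    }
    cut <- has_cp & !bad
    records$sequence[cut] <- substr(records$sequence[cut], 1L, cp[cut])
    records <- records[!bad, , drop = FALSE]
  }
  attr(records, "rejections") <- rejections
  records
}

#' Write peptides as FASTA plus the metadata table
#'
#' The inverse of [read_peptides()] (without cleavage positions: sequences
#' are written as-is).
#'
#' @param records peptide record table.
#' @param fasta_path output FASTA path.
#' @param metadata_path output TSV path.
#' @export
write_peptides <- function(records, fasta_path, metadata_path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, fasta_path)
  meta <- data.frame(
    id = records$id,
    seq_type = records$seq_type,
    lineage = vapply(records$lineage, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(records)
}
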