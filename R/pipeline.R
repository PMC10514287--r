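#' Validated run configuration for the end-to-end pipeline
#'
#' @param fasta,metadata input paths (see [read_peptides()]).
#' @param seq_types sequence types to analyze; `NULL` = every type present.
#' @param k_range motif sizes, subset of 2:5.
#' @param alphabet `"full"` or one of the reduced alphabets (`"enc7"`,
#'   `"enc8"`, `"enc10"`), or a `reduced_alphabet` object.
#' @param thresholds per-size frequency cutoffs for the top-motif report.
#' @param taxa optional character vector of exactly two taxon names to
#'   compare.
#' @param alpha significance level for the taxon comparison.
#' @param n_bins bins of the positional profiles.
#' @param min_occurrences minimum occurrences for a supported region call.
#' @param min_fraction minimum enriched-group fraction for taxon-specific
#'   calls.
#' @param out_dir output directory (created if missing).
#' @return object of class `run_config`.
#' @export
run_config <- function(fasta, metadata, seq_types = NULL, k_range = 2:5,
                       alphabet = "full", thresholds = default_thresholds(),
                       taxa = NULL, alpha = 0.05, n_bins = 20L,
                       min_occurrences = 20L, min_fraction = 0.1,
                       out_dir = "motif_run") {
  if (!file.exists(fasta)) stop("FASTA input not found: ", fasta, call. = FALSE)
  if (!file.exists(metadata)) stop("metadata input not found: ", metadata, call. = FALSE)
  stopifnot(all(k_range %in% 2:5), alpha > 0, alpha < 1, n_bins >= 3)
  if (is.character(alphabet) && alphabet != "full") {
    alphabet <- builtin_alphabet(alphabet)
  }
  if (!is.null(taxa) && length(taxa) != 2L) {
    stop("taxa must name exactly two groups to compare", call. = FALSE)
  }
  structure(list(fasta = fasta, metadata = metadata, seq_types = seq_types,
                 k_range = as.integer(k_range), alphabet = alphabet,
                 thresholds = thresholds, taxa = taxa, alpha = alpha,
                 n_bins = as.integer(n_bins),
                 min_occurrences = as.integer(min_occurrences),
                 min_fraction = min_fraction, out_dir = out_dir),
            class = "run_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Frequency tables for human reading carry a percent column rounded to one
# decimal; the fraction column keeps full precision.
.with_percent <- function(tab) {
  tab$percent <- round(100 * tab$fraction, 1)
  tab
}

#' Run the full motif-characterization pipeline
#'
#' Reads and filters the peptides, then per sequence type: counts every
#' observed gapped motif (presence and occurrence modes), derives frequency
#' tables (full and thresholded), repeat statistics, positional profiles and
#' region calls for the top motifs, and — when two taxa are configured —
#' Mann-Whitney/Benjamini-Hochberg comparisons with taxon-specific calls.
#' All tables are written as TSV under the configured output directory,
#' alongside a JSON run manifest (configuration, package version, input
#' checksums). The bundle is a pure function of (inputs, config): identical
#' inputs reproduce identical files.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the in-memory results per sequence type
#'   (`filter_report`, `frequency`, `top`, `repeats`, `regions`,
#'   `comparison`, `taxon_specific`) and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_peptides(config$fasta, config$metadata)
  types <- config$seq_types
  if (is.null(types)) types <- intersect(SEQ_TYPES, unique(records$seq_type))
  alph <- if (is.character(config$alphabet)) NULL else config$alphabet
  alph_name <- if (is.null(alph)) "full" else alph$name

  bundle <- list()
  for (st in types) {
    sub <- records[records$seq_type == st, , drop = FALSE]
    fl <- filter_dataset(sub, min_len = 10L,
                         max_len = if (st == "AMP") 100L else NULL)
    out <- list(filter_report = fl$report, n = nrow(fl$records))
    prefix <- file.path(config$out_dir, paste0(st, "_", alph_name))
    write_filter_report(fl$report, paste0(prefix, "_filter_report.json"))
    if (nrow(fl$records) > 0L) {
      pres <- count_matrix(fl$records, config$k_range, mode = "presence",
                           alphabet = alph)
      freq <- frequency_table(pres, seq_type = st, alphabet_name = alph_name)
      top <- top_motifs(freq, config$thresholds)
      reps <- repeat_analysis(fl$records, config$k_range, alphabet = alph)
      .write_tsv(.with_percent(freq), paste0(prefix, "_frequencies.tsv"))
      .write_tsv(.with_percent(top), paste0(prefix, "_top_motifs.tsv"))
      .write_tsv(reps, paste0(prefix, "_repeats.tsv"))

      regions <- lapply(top$motif, function(m) {
        prof <- positional_profile(fl$records, if (is.null(alph)) m else m,
                                   n_bins = config$n_bins, alphabet = alph)
        classify_region(prof, min_n = config$min_occurrences)
      })
      region_tab <- tibble::tibble(
        motif = vapply(regions, `[[`, character(1), "motif"),
        region = vapply(regions, `[[`, character(1), "region"),
        first_third = vapply(regions, function(r) r$thirds[["first"]], numeric(1)),
        middle_third = vapply(regions, function(r) r$thirds[["middle"]], numeric(1)),
        last_third = vapply(regions, function(r) r$thirds[["last"]], numeric(1)),
        n = vapply(regions, `[[`, integer(1), "n"),
        low_support = vapply(regions, `[[`, logical(1), "low_support")
      )
      .write_tsv(region_tab, paste0(prefix, "_regions.tsv"))
      out <- c(out, list(frequency = freq, top = top, repeats = reps,
                         regions = region_tab))

      if (!is.null(config$taxa)) {
        groups <- group_by_taxon(fl$records, config$taxa)
        if (all(vapply(groups, nrow, integer(1)) >= 2L)) {
          cnt <- count_matrix(fl$records, config$k_range, mode = "count",
                              alphabet = alph)
          cmp <- mann_whitney_bh(cnt, groups, alpha = config$alpha)
          calls <- taxon_specific_motifs(cmp, config$min_fraction)
          .write_tsv(cmp, paste0(prefix, "_taxon_comparison.tsv"))
          .write_tsv(calls, paste0(prefix, "_taxon_specific.tsv"))
          out <- c(out, list(comparison = cmp, taxon_specific = calls))
        }
      }
    }
    bundle[[st]] <- out
  }
  manifest <- list(
    package = "gappedmotifs",
    version = as.character(utils::packageVersion("gappedmotifs")),
    config = .manifest_config(config),
    inputs = list(fasta = unname(tools::md5sum(config$fasta)),
                  metadata = unname(tools::md5sum(config$metadata))),
    seq_types = types
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle$manifest <- manifest
  invisible(bundle)
}

.manifest_config <- function(config) {
  cf <- unclass(config)
  if (inherits(cf$alphabet, "reduced_alphabet")) {
    cf$alphabet <- cf$alphabet$name
  }
  cf
}
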