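#' One replicate of a two-group motif-comparison experiment
#'
#' Generates two independent peptide groups over a restricted uniform
#' background, plants a focal motif at a group-specific per-sequence rate in
#' each, counts all bigram-class motifs, and runs the Mann-Whitney /
#' Benjamini-Hochberg comparison. The focal motif's residues are kept out of
#' the background, so its presence fraction equals its planting rate, and
#' motifs built purely from background residues are genuine decoys whose
#' counts follow the same law in both groups: the focal motif is the only
#' true positive (when the rates differ) and every significant pure-decoy is
#' a false positive. Motifs mixing focal and background residues are a side
#' effect of the insertion and are excluded from the decoy rate.
#'
#' The restricted background (six residues by default) keeps the decoy family
#' dense enough for count-level tests at desk-scale sample sizes.
#'
#' @param n_per_group sequences per group.
#' @param rate_a,rate_b per-sequence planting probability of the focal motif
#'   in groups A and B (equal rates, e.g. both 0, give a global null).
#' @param motif focal motif (canonical string).
#' @param letters_used background residue subset (uniform over these).
#' @param length_range uniform length bounds.
#' @param k_range motif sizes counted.
#' @param alpha significance level.
#' @param seed replicate seed (two generator sub-seeds are derived from it).
#' @return list with `comparison` (the full test table), `focal` (the focal
#'   motif's row, zero rows if unobserved), `n_significant`, `n_tests`, and
#'   `decoy_fp_rate` (fraction of non-focal motifs called significant).
#' @export
two_group_replicate <- function(n_per_group = 100L, rate_a = 0.6, rate_b = 0.1,
                                motif = "S_S",
                                letters_used = c("A", "L", "K", "T", "G", "P"),
                                length_range = c(15L, 40L), k_range = 2L,
                                alpha = 0.05, seed = 1L) {
  bg <- setNames(rep(0, 20), AA_STANDARD)
  bg[letters_used] <- 1 / length(letters_used)
  mkspec <- function(prefix, rate, subseed) {
    generator_spec(n_per_group, "cTP", length_range, background = bg,
                   planted = if (rate > 0) {
                     tibble::tibble(motif = motif, prob = rate,
                                    position = "uniform")
                   },
                   id_prefix = prefix, seed = subseed)
  }
  gen_a <- generate_peptides(mkspec("A", rate_a, 2L * seed))
  gen_b <- generate_peptides(mkspec("B", rate_b, 2L * seed + 1L))
  records <- rbind(gen_a$records, gen_b$records)
  mat <- count_matrix(records, k_range = k_range, mode = "count")
  cmp <- mann_whitney_bh(mat, list(A = gen_a$records$id, B = gen_b$records$id),
                         alpha = alpha)
  focal <- cmp[cmp$motif == motif, , drop = FALSE]
  focal_letters <- unique(unlist(parse_motif(motif)$classes))
  pure_decoy <- cmp$motif != motif &
    !grepl(paste0("[", paste(focal_letters, collapse = ""), "]"), cmp$motif)
  decoys <- cmp[pure_decoy, , drop = FALSE]
  list(comparison = cmp, focal = focal,
       n_significant = sum(cmp$significant),
       n_tests = nrow(cmp),
       decoy_fp_rate = if (nrow(decoys)) mean(decoys$significant) else NA_real_)
}

#' Replicated two-group study: type-I control and detection power
#'
#' Runs [two_group_replicate()] `n_reps` times under the global null (equal
#' rates) and under the stated alternative, and summarizes: the pooled
#' fraction of motifs called significant under the null, the fraction of
#' replicates in which the focal motif is detected under the alternative,
#' and the pooled decoy false-positive rate under the alternative.
#'
#' @param n_reps replicates per condition.
#' @param rate_a,rate_b alternative-condition planting rates.
#' @param null_rate planting rate used in both groups under the null.
#' @inheritParams two_group_replicate
#' @return list with `null_sig_rate`, `null_n_tests`, `power`,
#'   `decoy_fp_rate`, `n_reps`.
#' @export
two_group_study <- function(n_reps = 200L, n_per_group = 100L, rate_a = 0.6,
                            rate_b = 0.1, null_rate = 0, motif = "S_S",
                            alpha = 0.05, seed = 1L) {
  null_sig <- 0L
  null_tests <- 0L
  detected <- logical(n_reps)
  fp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    nul <- two_group_replicate(n_per_group, null_rate, null_rate, motif,
                               alpha = alpha, seed = 10000L * seed + 2L * r)
    null_sig <- null_sig + nul$n_significant
    null_tests <- null_tests + nul$n_tests
    alt <- two_group_replicate(n_per_group, rate_a, rate_b, motif,
                               alpha = alpha, seed = 10000L * seed + 2L * r + 1L)
    detected[r] <- nrow(alt$focal) == 1L && alt$focal$significant
    fp[r] <- alt$decoy_fp_rate
  }
  list(null_sig_rate = null_sig / null_tests, null_n_tests = null_tests,
       power = mean(detected), decoy_fp_rate = mean(fp, na.rm = TRUE),
       n_reps = n_reps)
}
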