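#' Specification for the synthetic peptide generator
#'
#' Describes a dataset of independent random peptides: a length law (uniform
#' integers), a background residue distribution (optionally different inside
#' a scaled-coordinate window, emulating e.g. the hydrophobic mid-region of
#' signal peptides), a set of planted motifs with per-sequence insertion
#' probabilities and positional laws, and optional taxon structure with
#' per-taxon overrides.
#'
#' @param n number of sequences.
#' @param seq_type one of `"cTP"`, `"mTP"`, `"SP"`, `"AMP"`.
#' @param length_range integer bounds (inclusive) of the uniform length law;
#'   minimum length 10.
#' @param background named numeric of residue probabilities over the 20
#'   standard letters, summing to 1 (tolerance 1e-9). `NULL` = uniform.
#' @param region_background optional list with `from`, `to` (scaled 0-100
#'   coordinates, half-open window) and `background` (a residue
#'   distribution): positions whose scaled midpoint falls in the window draw
#'   from this distribution instead.
#' @param planted data frame with columns `motif` (canonical string over the
#'   full alphabet, singleton classes), `prob` (per-sequence insertion
#'   probability) and `position` (one of `"prefix"`, `"first-third"`,
#'   `"middle"`, `"uniform"`, `"last-third"`). `NULL` = nothing planted.
#' @param taxa optional list of taxon entries, each a list with `name`,
#'   `lineage` (character vector), `prop` (sampling proportion), and optional
#'   `background` and `planted` overrides (a taxon's `planted` replaces the
#'   shared one for its sequences).
#' @param id_prefix prefix for generated sequence ids.
#' @param seed integer seed making generation a pure function of the spec.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n, seq_type = "cTP", length_range = c(20L, 100L),
                           background = NULL, region_background = NULL,
                           planted = NULL, taxa = NULL,
                           id_prefix = seq_type, seed = 1L) {
  stopifnot(n >= 0, length(length_range) == 2L)
  length_range <- as.integer(length_range)
  if (length_range[1] < 10L || length_range[2] < length_range[1]) {
    stop("length range must be increasing with minimum >= 10", call. = FALSE)
  }
  background <- .check_background(background)
  if (!is.null(region_background)) {
    stopifnot(is.list(region_background),
              all(c("from", "to") %in% names(region_background)))
    region_background$background <- .check_background(region_background$background)
  }
  planted <- .check_planted(planted, length_range[1])
  if (!is.null(taxa)) {
    props <- vapply(taxa, `[[`, numeric(1), "prop")
    if (abs(sum(props) - 1) > 1e-9) stop("taxon proportions must sum to 1", call. = FALSE)
    taxa <- lapply(taxa, function(tx) {
      if (!is.null(tx$background)) tx$background <- .check_background(tx$background)
      if (!is.null(tx$planted)) tx$planted <- .check_planted(tx$planted, length_range[1])
      tx
    })
  }
  structure(list(n = as.integer(n), seq_type = seq_type,
                 length_range = length_range, background = background,
                 region_background = region_background, planted = planted,
                 taxa = taxa, id_prefix = id_prefix, seed = as.integer(seed)),
            class = "generator_spec")
}

.check_background <- function(background) {
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (!setequal(names(background), AA_STANDARD)) {
    stop("background must be named by the 20 standard letters", call. = FALSE)
  }
  background <- background[AA_STANDARD]
  if (any(background < 0) || abs(sum(background) - 1) > 1e-9) {
    stop("background probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  background
}

.POSITION_LAWS <- c("prefix", "first-third", "middle", "uniform", "last-third")

.check_planted <- function(planted, min_len) {
  if (is.null(planted) || nrow(planted) == 0L) return(NULL)
  stopifnot(all(c("motif", "prob", "position") %in% names(planted)))
  planted <- tibble::as_tibble(planted)
  pats <- lapply(planted$motif, parse_motif)
  spans <- vapply(pats, `[[`, integer(1), "span")
  if (any(spans > min_len)) {
    stop("planted motif span exceeds the minimum sequence length: ",
         planted$motif[spans > min_len][1], call. = FALSE)
  }
  if (any(planted$prob < 0 | planted$prob > 1)) {
    stop("insertion probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!all(planted$position %in% .POSITION_LAWS)) {
    stop("position must be one of ", paste(.POSITION_LAWS, collapse = ", "),
         call. = FALSE)
  }
  planted$pattern <- pats
  planted
}

# Admissible 1-based starts for a positional law, on the scaled axis used by
# the positional module (start midpoint (s - 0.5)/L * 100). Falls back to all
# valid starts when the law's window admits none.
.law_starts <- function(law, L, span) {
  valid <- seq_len(L - span + 1L)
  scaled <- 100 * (valid - 0.5) / L
  sel <- switch(law,
                prefix = valid[valid == 1L],
                `first-third` = valid[scaled < 100 / 3],
                middle = valid[scaled >= 100 / 3 & scaled < 200 / 3],
                `last-third` = valid[scaled >= 200 / 3],
                uniform = valid)
  if (length(sel) == 0L) valid else sel
}

#' Generate a synthetic peptide dataset with ground truth
#'
#' Background residues are drawn i.i.d. from the spec's distribution(s); each
#' planted motif is then inserted, per sequence with its stated probability,
#' at a start drawn uniformly from its positional law's admissible starts.
#' Insertions overwrite the specified residue positions in place (gap
#' positions keep their background letters), so the length law stays exact.
#' Later insertions may clobber earlier ones; the ground truth records every
#' insertion and whether it is still intact (re-detectable at its recorded
#' start) at the end.
#'
#' Generation is a pure function of the spec (including its seed): the same
#' spec yields byte-identical records.
#'
#' @param spec a `generator_spec`.
#' @return list with `records` (peptide record table) and `ground_truth`,
#'   itself a list with `insertions` (tibble: id, motif, start, intact) and
#'   `planted_fractions` (tibble: taxon, motif, frac_planted — the realized
#'   fraction of sequences that received an intact insertion).
#' @export
generate_peptides <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$n
  ids <- sprintf("%s_%05d", spec$id_prefix, seq_len(max(n, 1L)))[seq_len(n)]
  if (is.null(spec$taxa)) {
    taxon_of <- rep(NA_character_, n)
    lineages <- rep(list(character(0)), n)
  } else {
    tx_names <- vapply(spec$taxa, `[[`, character(1), "name")
    props <- vapply(spec$taxa, `[[`, numeric(1), "prop")
    taxon_of <- sample(tx_names, n, replace = TRUE, prob = props)
    lin_by_tx <- setNames(lapply(spec$taxa, `[[`, "lineage"), tx_names)
    lineages <- unname(lin_by_tx[taxon_of])
  }
  lens <- spec$length_range[1] - 1L +
    sample.int(spec$length_range[2] - spec$length_range[1] + 1L, n, replace = TRUE)

  seqs <- character(n)
  ins_id <- character(0); ins_motif <- character(0); ins_start <- integer(0)
  tx_index <- if (is.null(spec$taxa)) NULL else
    setNames(seq_along(spec$taxa), vapply(spec$taxa, `[[`, character(1), "name"))

  for (i in seq_len(n)) {
    L <- lens[i]
    bg <- spec$background
    planted <- spec$planted
    if (!is.null(spec$taxa)) {
      tx <- spec$taxa[[tx_index[[taxon_of[i]]]]]
      if (!is.null(tx$background)) bg <- tx$background
      if (!is.null(tx$planted)) planted <- tx$planted
    }
    chars <- sample(AA_STANDARD, L, replace = TRUE, prob = bg)
    rb <- spec$region_background
    if (!is.null(rb)) {
      mid <- 100 * (seq_len(L) - 0.5) / L
      inwin <- mid >= rb$from & mid < rb$to
      if (any(inwin)) {
        chars[inwin] <- sample(AA_STANDARD, sum(inwin), replace = TRUE,
                               prob = rb$background)
      }
    }
    if (!is.null(planted)) {
      for (j in seq_len(nrow(planted))) {
        if (stats::runif(1) >= planted$prob[j]) next
        pat <- planted$pattern[[j]]
        starts <- .law_starts(planted$position[j], L, pat$span)
        s <- if (length(starts) == 1L) starts else sample(starts, 1L)
        offsets <- cumsum(c(0L, pat$gaps + 1L))
        for (ci in seq_along(pat$classes)) {
          cl <- pat$classes[[ci]]
          chars[s + offsets[ci]] <- if (length(cl) == 1L) cl else sample(cl, 1L)
        }
        ins_id <- c(ins_id, ids[i])
        ins_motif <- c(ins_motif, planted$motif[j])
        ins_start <- c(ins_start, s)
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }

  records <- peptide_records(ids, seqs, spec$seq_type, lineages)
  intact <- logical(length(ins_id))
  if (length(ins_id)) {
    seq_by_id <- setNames(seqs, ids)
    pats <- setNames(lapply(unique(ins_motif), parse_motif), unique(ins_motif))
    for (r in seq_along(ins_id)) {
      chars <- strsplit(seq_by_id[[ins_id[r]]], "", fixed = TRUE)[[1]]
      intact[r] <- ins_start[r] %in% .match_starts(chars, pats[[ins_motif[r]]])
    }
  }
  insertions <- tibble::tibble(id = ins_id, motif = ins_motif,
                               start = ins_start, intact = intact)
  frac <- .planted_fractions(insertions, taxon_of, ids, n)
  list(records = records,
       ground_truth = list(insertions = insertions, planted_fractions = frac,
                           taxon_of = setNames(taxon_of, ids)))
}

.planted_fractions <- function(insertions, taxon_of, ids, n) {
  if (nrow(insertions) == 0L) {
    return(tibble::tibble(taxon = character(0), motif = character(0),
                          frac_planted = numeric(0)))
  }
  ok <- insertions[insertions$intact, , drop = FALSE]
  tx <- taxon_of[match(ok$id, ids)]
  tx[is.na(tx)] <- "all"
  key <- unique(data.frame(taxon = tx, motif = ok$motif, id = ok$id,
                           stringsAsFactors = FALSE))
  denom <- table(factor(ifelse(is.na(taxon_of), "all", taxon_of)))
  agg <- stats::aggregate(id ~ taxon + motif, data = key, FUN = length)
  tibble::tibble(taxon = agg$taxon, motif = agg$motif,
                 frac_planted = agg$id / as.numeric(denom[agg$taxon]))
}

#' Built-in generator presets
#'
#' Qualitative emulations of the composition and motif structure of each
#' peptide class — not fits to any real dataset:
#' \itemize{
#'   \item `cTP-like`: serine-rich background (lengths 20-100), `MA` planted
#'     as a prefix at rate 0.8, `SS` and `S_S` planted uniformly at 0.7.
#'   \item `mTP-like`: arginine/leucine-rich background (lengths 15-80),
#'     `LR`, `L_R`, `R_L` planted uniformly at 0.5/0.5/0.45 and `AAA` at 0.15.
#'   \item `SP-like`: leucine-rich mid-region (scaled window 35-70, lengths
#'     15-40), `LL` and `LLL` planted in the middle at 0.65/0.30.
#'   \item `AMP-like`: lysine-rich background (lengths 10-100), `KK` and
#'     `K___K` planted uniformly at 0.40/0.35.
#'   \item `two-taxon-demo`: two equal-sized cTP-like taxa (Streptophyta-like
#'     vs Chlorophyta-like lineages, lengths 20-50). The first carries `SP`
#'     (rate 0.6; its counterpart draws no proline at all, so `SP` is
#'     exclusive) and `S_S` at 0.6; the second carries `S_S` at 0.1 only.
#' }
#'
#' @param name preset name (see above).
#' @param n number of sequences (default 1000).
#' @param seed generation seed.
#' @return a `generator_spec`.
#' @export
preset_spec <- function(name = c("cTP-like", "mTP-like", "SP-like", "AMP-like",
                                 "two-taxon-demo"), n = 1000L, seed = 1L) {
  name <- match.arg(name)
  bg <- function(...) {
    w <- c(...)
    rest <- setdiff(AA_STANDARD, names(w))
    out <- setNames(rep((1 - sum(w)) / length(rest), length(rest)), rest)
    .check_background(c(w, out))
  }
  pl <- function(motif, prob, position) {
    tibble::tibble(motif = motif, prob = prob, position = position)
  }
  switch(name,
    "cTP-like" = generator_spec(
      n, "cTP", c(20L, 100L),
      background = bg(S = 0.18, A = 0.12, L = 0.10, P = 0.07),
      # the prefix motif is planted last: the N-terminal identity should
      # dominate interior plants when insertions collide at positions 1-2
      planted = pl(c("SS", "S_S", "MA"), c(0.70, 0.70, 0.80),
                   c("uniform", "uniform", "prefix")),
      id_prefix = "cTP", seed = seed),
    "mTP-like" = generator_spec(
      n, "mTP", c(15L, 80L),
      background = bg(R = 0.13, L = 0.13, A = 0.12, S = 0.09),
      planted = pl(c("LR", "L_R", "R_L", "AAA"), c(0.50, 0.50, 0.45, 0.15),
                   rep("uniform", 4)),
      id_prefix = "mTP", seed = seed),
    "SP-like" = generator_spec(
      n, "SP", c(15L, 40L),
      background = bg(L = 0.08, A = 0.10),
      region_background = list(from = 35, to = 70,
                               background = bg(L = 0.45, A = 0.15)),
      planted = pl(c("LL", "LLL"), c(0.65, 0.30), c("middle", "middle")),
      id_prefix = "SP", seed = seed),
    "AMP-like" = generator_spec(
      n, "AMP", c(10L, 100L),
      background = bg(K = 0.15, L = 0.10, A = 0.08, I = 0.07, G = 0.07, C = 0.06),
      planted = pl(c("KK", "K___K"), c(0.40, 0.35), c("uniform", "uniform")),
      id_prefix = "AMP", seed = seed),
    "two-taxon-demo" = generator_spec(
      n, "cTP", c(20L, 50L),
      background = bg(S = 0.08, A = 0.10, P = 0.05),
      taxa = list(
        list(name = "Streptophyta",
             lineage = c("Eukaryota", "Viridiplantae", "Streptophyta"),
             prop = 0.5,
             planted = pl(c("SP", "S_S"), c(0.60, 0.60),
                          c("uniform", "uniform"))),
        list(name = "Chlorophyta",
             lineage = c("Eukaryota", "Viridiplantae", "Chlorophyta"),
             prop = 0.5,
             background = bg(S = 0.08, A = 0.10, P = 0),
             planted = pl("S_S", 0.10, "uniform"))
      ),
      id_prefix = "cTP", seed = seed)
  )
}

#' Plant filter violations into a clean record set
#'
#' Modifies disjoint subsets of a clean (already standard-letter, in-range)
#' record set so that the dataset filter's per-step ledger has exact known
#' ground truth: `n_nonstandard` records get one residue replaced by `X`,
#' `n_short` are truncated below the minimum length, `n_long` are extended
#' beyond `long_to` residues, and `n_duplicate` later records have their
#' sequence overwritten with that of an earlier untouched record.
#'
#' @param records clean peptide record table (needs at least
#'   `n_nonstandard + n_short + n_long + 2 * n_duplicate` rows).
#' @param n_nonstandard,n_short,n_long,n_duplicate planted counts.
#' @param short_to length the shortened sequences are truncated to.
#' @param long_to minimum length of the lengthened sequences.
#' @param seed seed for choosing the affected records.
#' @return list with `records` (the corrupted set, same row count) and
#'   `planted` (named counts, the expected filter ledger entries).
#' @export
plant_filter_violations <- function(records, n_nonstandard = 0L, n_short = 0L,
                                    n_long = 0L, n_duplicate = 0L,
                                    short_to = 5L, long_to = 101L, seed = 1L) {
  need <- n_nonstandard + n_short + n_long + 2L * n_duplicate
  if (nrow(records) < need) stop("not enough records to corrupt", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  idx <- sample(nrow(records), need)
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  i_non <- take(n_nonstandard)
  i_short <- take(n_short)
  i_long <- take(n_long)
  i_dup <- take(2L * n_duplicate)

  for (i in i_non) {
    s <- records$sequence[i]
    pos <- sample(nchar(s), 1L)
    substr(records$sequence[i], pos, pos) <- "X"
  }
  records$sequence[i_short] <- substr(records$sequence[i_short], 1L, short_to)
  for (i in i_long) {
    s <- records$sequence[i]
    records$sequence[i] <- substr(strrep(s, ceiling(long_to / nchar(s)) + 1L),
                                  1L, long_to)
  }
  if (n_duplicate > 0L) {
    pairs <- matrix(i_dup, ncol = 2L)
    src <- pmin(pairs[, 1], pairs[, 2])
    dst <- pmax(pairs[, 1], pairs[, 2])
    records$sequence[dst] <- records$sequence[src]
  }
  list(records = records,
       planted = c(nonstandard = n_nonstandard, short = n_short,
                   long = n_long, duplicate = n_duplicate))
}
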