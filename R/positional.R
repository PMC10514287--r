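#' Motif start positions on the length-scaled axis
#'
#' Sequence lengths are scaled to 100 so that positional preferences are
#' comparable across peptides of different lengths. An occurrence starting at
#' 1-based position `s` in a sequence of length `L` maps to
#' `100 * (s - 0.5) / L`, which lies strictly inside (0, 100) and places the
#' first position near, but not at, zero.
#'
#' @param records peptide record table.
#' @param pattern a `motif_pattern` or canonical motif string.
#' @param alphabet optional `reduced_alphabet`: sequences are recoded and the
#'   pattern is interpreted over the group rendering.
#' @return numeric vector of scaled start positions (one per occurrence,
#'   pooled over all sequences).
#' @export
scaled_positions <- function(records, pattern, alphabet = NULL) {
  pattern <- .as_pattern(pattern)
  seqs <- records$sequence
  if (!is.null(alphabet)) {
    seqs <- recode(seqs, alphabet)
    pattern <- .reduce_pattern_to_symbols(pattern, alphabet)
  }
  out <- lapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    starts <- .match_starts(chars, pattern)
    if (length(starts) == 0L) return(numeric(0))
    100 * (starts - 0.5) / length(chars)
  })
  unlist(out, use.names = FALSE)
}

# Translate a bracketed/reduced motif pattern into the alphabet's internal
# single-symbol classes so it can be matched against recoded sequences.
.reduce_pattern_to_symbols <- function(pattern, alphabet) {
  classes <- lapply(pattern$classes, function(cl) {
    if (all(cl %in% names(alphabet$lookup))) {
      # letters: map through group membership (class must sit inside groups)
      unique(unname(alphabet$lookup[cl]))
    } else if (all(cl %in% alphabet$symbols)) {
      cl
    } else {
      stop("motif class not expressible in alphabet '", alphabet$name, "'",
           call. = FALSE)
    }
  })
  motif_pattern(classes, pattern$gaps, check_shape = FALSE)
}

#' Positional start-density profile
#'
#' Histogram of scaled start positions (default 20 bins of width 5 on the
#' 0-100 axis), normalized to unit mass when any occurrences exist.
#'
#' @inheritParams scaled_positions
#' @param n_bins number of equal-width bins on the 0-100 axis.
#' @return object of class `positional_profile`: list with `motif`,
#'   `breaks`, `mids`, `mass` and `n` (number of occurrences).
#' @export
positional_profile <- function(records, pattern, n_bins = 20L, alphabet = NULL) {
  pattern <- .as_pattern(pattern)
  pos <- scaled_positions(records, pattern, alphabet = alphabet)
  breaks <- seq(0, 100, length.out = n_bins + 1L)
  counts <- if (length(pos)) {
    tabulate(findInterval(pos, breaks, rightmost.closed = TRUE), nbins = n_bins)
  } else {
    rep(0L, n_bins)
  }
  mass <- if (length(pos)) counts / length(pos) else rep(0, n_bins)
  structure(list(motif = format_motif(pattern), breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 mass = mass, n = length(pos)),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("<positional_profile> ", x$motif, ": n=", x$n, "\n", sep = "")
  invisible(x)
}

#' Classify a motif's preferred region from its positional profile
#'
#' A deterministic rule on the profile's thirds (first: scaled position
#' below 35; middle: 35 to below 70; last: 70 and above), formalizing the
#' qualitative region annotations used to describe motif positioning:
#' \itemize{
#'   \item `N-terminus` if at least `nterm` of the mass falls below scaled
#'     position 10 (the first two default bins);
#'   \item `first-part` / `middle` if at least `dominant` of the mass falls
#'     in the first / middle third;
#'   \item `C-depleted` if the last third carries less than `depleted` of the
#'     mass and none of the above applies;
#'   \item `C-enriched` if the last third carries at least `enriched_ratio`
#'     times the mass of each other third;
#'   \item `whole` otherwise.
#' }
#' Profiles with fewer than `min_n` occurrences are labelled `whole` with a
#' low-support flag.
#'
#' @param profile a `positional_profile`.
#' @param min_n minimum number of occurrences for a supported call.
#' @param nterm,dominant,depleted,enriched_ratio rule cutoffs (see above).
#' @return list of class `region_call` with `motif`, `region`, `thirds`
#'   (named first/middle/last masses), `nterm_mass`, `n`, `low_support`.
#' @export
classify_region <- function(profile, min_n = 20L, nterm = 0.5, dominant = 0.6,
                            depleted = 0.05, enriched_ratio = 2) {
  stopifnot(inherits(profile, "positional_profile"))
  mids <- profile$mids
  m <- profile$mass
  thirds <- c(first = sum(m[mids < 35]),
              middle = sum(m[mids >= 35 & mids < 70]),
              last = sum(m[mids >= 70]))
  nterm_mass <- sum(m[mids < 10])
  low_support <- profile$n < min_n
  region <- if (low_support) {
    "whole"
  } else if (nterm_mass >= nterm) {
    "N-terminus"
  } else if (thirds[["first"]] >= dominant) {
    "first-part"
  } else if (thirds[["middle"]] >= dominant) {
    "middle"
  } else if (thirds[["last"]] < depleted) {
    "C-depleted"
  } else if (thirds[["last"]] >= enriched_ratio * thirds[["first"]] &&
             thirds[["last"]] >= enriched_ratio * thirds[["middle"]]) {
    "C-enriched"
  } else {
    "whole"
  }
  structure(list(motif = profile$motif, region = region, thirds = thirds,
                 nterm_mass = nterm_mass, n = profile$n,
                 low_support = low_support),
            class = "region_call")
}

#' @export
print.region_call <- function(x, ...) {
  cat("<region_call> ", x$motif, ": ", x$region,
      if (x$low_support) " (low support)", " [thirds ",
      paste(sprintf("%.2f", x$thirds), collapse = "/"), ", n=", x$n, "]\n",
      sep = "")
  invisible(x)
}

#' Fraction of sequences starting with an exact prefix
#'
#' The positional claim most directly checkable without any histogram: e.g.
#' the fraction of chloroplast transit peptides whose first two residues are
#' `MA`.
#'
#' @param records peptide record table.
#' @param prefix residue prefix string.
#' @return fraction in [0, 1].
#' @export
prefix_fraction <- function(records, prefix = "MA") {
  if (nrow(records) == 0L) return(NaN)
  mean(startsWith(records$sequence, prefix))
}
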