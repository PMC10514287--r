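# Per-slot gap bounds for motif sizes 2..4; size 5 is handled separately
# (contiguous, or exactly one single-residue gap).
.GAP_LIMITS <- c(`2` = 3L, `3` = 3L, `4` = 2L)
.MAX_SPAN <- 10L

#' Enumerate gap shapes for a motif size
#'
#' A gapped motif of size k consists of k specified residues separated by
#' fixed numbers of unspecified positions (gaps). The shapes considered are:
#' sizes 2 and 3 allow zero to three unspecified residues per gap slot,
#' size 4 allows zero to two, and size 5 allows either no gaps or exactly one
#' gap of a single unspecified residue. Every shape has a total footprint
#' (span = size + total gap length) of at most 10 positions.
#'
#' @param k motif size (number of specified residues), one of 2, 3, 4, 5.
#' @param max_gap optional override of the per-slot gap bound for k in 2..4
#'   (the size-5 rule is structural and not affected).
#' @return list of integer gap tuples (each of length `k - 1`), in
#'   lexicographic order.
#' @examples
#' enumerate_shapes(2) # list(0L, 1L, 2L, 3L)
#' length(enumerate_shapes(4)) # 27
#' @export
enumerate_shapes <- function(k, max_gap = NULL) {
  if (length(k) != 1L || is.na(k) || !(k %in% 2:5)) {
    stop("motif size k must be one of 2, 3, 4, 5", call. = FALSE)
  }
  k <- as.integer(k)
  if (k %in% 2:4) {
    bound <- if (is.null(max_gap)) .GAP_LIMITS[[as.character(k)]] else as.integer(max_gap)
    grid <- expand.grid(rep(list(0L:bound), k - 1L))
    grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
    shapes <- lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  } else {
    shapes <- c(list(rep(0L, 4L)),
                lapply(4:1, function(i) {
                  g <- rep(0L, 4L)
                  g[i] <- 1L
                  g
                }))
    # lexicographic: (0,0,0,0) < (0,0,0,1) < (0,0,1,0) < (0,1,0,0) < (1,0,0,0)
  }
  shapes[vapply(shapes, function(g) k + sum(g) <= .MAX_SPAN, logical(1))]
}

#' Construct a gapped motif pattern
#'
#' @param classes list of residue classes; each class is a non-empty character
#'   vector of single uppercase letters (singletons on the full alphabet,
#'   larger sets for reduced-alphabet motifs).
#' @param gaps integer vector of gap lengths between adjacent classes
#'   (`length(classes) - 1` entries, each >= 0).
#' @param check_shape if TRUE (default), require the gap tuple to be one of
#'   the shapes `enumerate_shapes()` yields for this motif size.
#' @return an object of class `motif_pattern` with elements `classes`,
#'   `gaps`, `k` and `span`.
#' @export
motif_pattern <- function(classes, gaps = integer(0), check_shape = TRUE) {
  if (!is.list(classes)) classes <- lapply(classes, identity)
  k <- length(classes)
  if (k < 2L || k > 5L) {
    stop("a motif must have between 2 and 5 residue classes, got ", k, call. = FALSE)
  }
  classes <- lapply(classes, function(cl) {
    cl <- sort(unique(as.character(cl)))
    if (length(cl) == 0L || any(nchar(cl) != 1L)) {
      stop("every residue class must be a non-empty set of single letters", call. = FALSE)
    }
    cl
  })
  gaps <- as.integer(gaps)
  if (length(gaps) != k - 1L) {
    stop("need ", k - 1L, " gap lengths for ", k, " classes, got ", length(gaps), call. = FALSE)
  }
  if (any(gaps < 0L)) stop("gap lengths must be non-negative", call. = FALSE)
  span <- k + sum(gaps)
  if (span > .MAX_SPAN) {
    stop("motif span ", span, " exceeds the maximum of ", .MAX_SPAN, call. = FALSE)
  }
  if (check_shape) {
    ok <- any(vapply(enumerate_shapes(k), identical, logical(1), y = gaps))
    if (!ok) {
      stop("gap tuple (", paste(gaps, collapse = ","),
           ") is not an allowed shape for motif size ", k, call. = FALSE)
    }
  }
  structure(list(classes = classes, gaps = gaps, k = k, span = as.integer(span)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", format_motif(x), " (k=", x$k, ", span=", x$span, ")\n",
      sep = "")
  invisible(x)
}

#' Parse a canonical motif string
#'
#' Canonical notation: one letter (or one bracketed letter set, e.g.
#' `"[AVIL]"`) per specified residue, with one underscore per unspecified
#' position, e.g. `"S_S"` (one-residue gap) or `"S__S"` (two-residue gap).
#'
#' @param text a single motif string.
#' @param check_shape passed to [motif_pattern()].
#' @return a `motif_pattern`.
#' @export
parse_motif <- function(text, check_shape = TRUE) {
  if (length(text) != 1L || !is.character(text) || is.na(text) || nchar(text) == 0L) {
    stop("motif text must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  classes <- list()
  gaps <- integer(0)
  pending_gap <- 0L
  seen_class <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "_") {
      if (!seen_class) stop("motif cannot start with '_': ", text, call. = FALSE)
      pending_gap <- pending_gap + 1L
      i <- i + 1L
    } else {
      if (ch == "[") {
        close <- which(chars == "]" & seq_len(n) > i)
        if (length(close) == 0L) stop("unclosed '[' in motif: ", text, call. = FALSE)
        close <- close[1]
        members <- chars[(i + 1L):(close - 1L)]
        if (close == i + 1L) stop("empty residue class '[]' in motif: ", text, call. = FALSE)
        cl <- members
        i <- close + 1L
      } else if (grepl("^[A-Za-z]$", ch)) {
        cl <- ch
        i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in motif: ", text, call. = FALSE)
      }
      if (seen_class) {
        gaps <- c(gaps, pending_gap)
        pending_gap <- 0L
      }
      classes <- c(classes, list(cl))
      seen_class <- TRUE
    }
  }
  if (pending_gap > 0L) stop("motif cannot end with '_': ", text, call. = FALSE)
  motif_pattern(classes, gaps, check_shape = check_shape)
}

#' Render a motif pattern as its canonical string
#'
#' Singleton classes render as the bare letter; multi-letter classes as a
#' bracketed, alphabetically sorted set. `parse_motif(format_motif(p))`
#' reproduces `p`.
#'
#' @param pattern a `motif_pattern`.
#' @return canonical motif string.
#' @export
format_motif <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  cls <- vapply(pattern$classes, function(cl) {
    if (length(cl) == 1L) cl else paste0("[", paste(cl, collapse = ""), "]")
  }, character(1))
  seps <- c(vapply(pattern$gaps, function(g) strrep("_", g), character(1)), "")
  paste0(paste0(cls, seps), collapse = "")
}

.as_pattern <- function(x, check_shape = TRUE) {
  if (inherits(x, "motif_pattern")) x else parse_motif(x, check_shape = check_shape)
}

#' Find all occurrences of a motif in one sequence
#'
#' Occurrences may overlap; every matching start position is reported.
#' A start position s (1-based) matches when, for every class i of the
#' pattern, the sequence letter at s + offset_i belongs to class i, where
#' offset_i counts the specified residues and gaps preceding class i.
#' Unspecified (gap) positions match any letter.
#'
#' @param sequence a single residue string.
#' @param pattern a `motif_pattern` or canonical motif string.
#' @return list with `motif` (canonical string), `count`, and `starts`
#'   (1-based start positions).
#' @examples
#' find_occurrences("MASSS", "S_S") # one occurrence starting at position 3
#' find_occurrences("LLLL", "LL")$count # 3 overlapping occurrences
#' @export
find_occurrences <- function(sequence, pattern) {
  pattern <- .as_pattern(pattern)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  starts <- .match_starts(chars, pattern)
  list(motif = format_motif(pattern), count = length(starts), starts = starts)
}

.match_starts <- function(chars, pattern) {
  L <- length(chars)
  n_starts <- L - pattern$span + 1L
  if (n_starts < 1L) return(integer(0))
  offsets <- cumsum(c(0L, pattern$gaps + 1L))
  ok <- rep(TRUE, n_starts)
  starts <- seq_len(n_starts)
  for (i in seq_along(pattern$classes)) {
    ok <- ok & chars[starts + offsets[i]] %in% pattern$classes[[i]]
  }
  starts[ok]
}

#' Count every observed gapped motif across a sequence set
#'
#' Enumerates, for every shape of every requested motif size, all motif
#' instantiations actually present in the sequences (motifs absent from every
#' sequence are never materialized), and assembles a sparse motif-by-sequence
#' matrix. In `presence` mode entries are 0/1 flags; in `count` mode they are
#' occurrence counts (overlapping occurrences at distinct starts all count).
#'
#' @param records a peptide record table (see [peptide_records()]); only the
#'   `sequence` and `id` columns are used.
#' @param k_range motif sizes to include, subset of 2:5.
#' @param mode `"presence"` or `"count"`.
#' @param alphabet optional `reduced_alphabet`; sequences are recoded before
#'   counting and motif row names use the bracketed group rendering.
#' @param max_gap optional per-slot gap bound override (see
#'   [enumerate_shapes()]).
#' @return a `Matrix::dgCMatrix` with canonical motif strings as row names
#'   and sequence ids as column names, rows ordered by motif size, shape,
#'   then residues.
#' @export
count_matrix <- function(records, k_range = 2:5, mode = c("presence", "count"),
                         alphabet = NULL, max_gap = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(k_range %in% 2:5))
  ids <- records$id
  seqs <- records$sequence
  n <- length(seqs)
  if (n == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, 0L),
                                dimnames = list(character(0), character(0))))
  }
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  if (!is.null(alphabet)) seqs <- recode(seqs, alphabet)

  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  big <- unlist(chars, use.names = FALSE)
  seq_off <- cumsum(c(0L, lens[-n]))

  pieces <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    for (g in enumerate_shapes(k, max_gap = max_gap)) {
      span <- k + sum(g)
      ns <- pmax(lens - span + 1L, 0L)
      total <- sum(ns)
      if (total == 0L) next
      sidx <- rep.int(seq_len(n), ns)
      starts <- rep.int(seq_off, ns) + sequence(ns)
      offsets <- cumsum(c(0L, g + 1L))
      parts <- vector("list", 2L * k - 1L)
      for (i in seq_len(k)) {
        parts[[2L * i - 1L]] <- big[starts + offsets[i]]
        if (i < k) parts[[2L * i]] <- strrep("_", g[i])
      }
      mstr <- do.call(paste0, parts)
      dt <- data.table::data.table(motif = mstr, seq = sidx)
      dt <- dt[, list(value = .N), by = c("motif", "seq")]
      dt[, `:=`(k = k, shape = paste(g, collapse = ","))]
      pieces[[length(pieces) + 1L]] <- dt
    }
  }
  if (length(pieces) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, n), dimnames = list(character(0), ids)))
  }
  all_dt <- data.table::rbindlist(pieces)
  motif_index <- unique(all_dt[, c("motif", "k", "shape")])
  data.table::setorderv(motif_index, c("k", "shape", "motif"))
  motif_index[, row := .I]
  all_dt <- motif_index[all_dt, on = c("motif", "k", "shape")]

  x <- if (mode == "presence") rep(1, nrow(all_dt)) else as.numeric(all_dt$value)
  rn <- motif_index$motif
  if (!is.null(alphabet)) rn <- render_motif(rn, alphabet)
  Matrix::sparseMatrix(i = all_dt$row, j = all_dt$seq, x = x,
                       dims = c(nrow(motif_index), n),
                       dimnames = list(rn, ids))
}

#' Parse canonical motif strings into size/shape metadata
#'
#' @param motifs character vector of canonical motif strings (bare letters or
#'   bracketed classes).
#' @return a tibble with columns `motif`, `k`, `shape` (comma-separated gap
#'   lengths) and `span`.
#' @export
motif_info <- function(motifs) {
  # a motif's size/shape depends only on its gap template, of which there are
  # at most 52 — collapse classes to one symbol and parse each template once
  collapsed <- gsub("\\[[^]]+\\]", "X", motifs)
  templates <- gsub("[^_]", "X", collapsed)
  uniq <- unique(templates)
  meta <- lapply(uniq, function(tpl) {
    chars <- strsplit(tpl, "", fixed = TRUE)[[1]]
    pos <- which(chars != "_")
    list(k = length(pos), shape = paste(diff(pos) - 1L, collapse = ","),
         span = length(chars))
  })
  idx <- match(templates, uniq)
  tibble::tibble(
    motif = motifs,
    k = vapply(meta, `[[`, integer(1), "k")[idx],
    shape = vapply(meta, `[[`, character(1), "shape")[idx],
    span = vapply(meta, `[[`, integer(1), "span")[idx]
  )
}
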