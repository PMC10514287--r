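# Built-in reduced alphabets grouping the 20 standard residues by
# physicochemical character: small hydrophobic, polar uncharged, positively
# charged, negatively charged, aromatic, special (C/G/P), and methionine.
# enc8 splits the hydroxylated pair S/T from the amides N/Q; enc10 further
# isolates alanine and arginine.
.BUILTIN_ALPHABETS <- list(
  enc7  = c("AVIL", "STNQ", "RHK", "DE", "FYW", "CGP", "M"),
  enc8  = c("AVIL", "ST", "NQ", "RHK", "DE", "FYW", "CGP", "M"),
  enc10 = c("VIL", "A", "ST", "NQ", "R", "HK", "DE", "FYW", "CGP", "M")
)

#' Construct a reduced amino-acid alphabet
#'
#' A reduced alphabet partitions the 20 standard amino-acid letters into
#' disjoint, exhaustive groups; sequences recoded group-wise can be fed to
#' the motif engine unchanged. Internally each group is a single lowercase
#' symbol; externally groups render as bracketed letter sets in the group's
#' stated order (a bare letter for singleton groups), e.g. `"[AVIL]"` or
#' `"R"`.
#'
#' @param groups character vector, one group per element, each a string of
#'   amino-acid letters (e.g. `"AVIL"`).
#' @param name a label for the alphabet.
#' @return an object of class `reduced_alphabet`.
#' @export
reduced_alphabet <- function(groups, name = "custom") {
  members <- lapply(groups, function(g) unique(strsplit(toupper(g), "")[[1]]))
  flat <- unlist(members)
  if (anyDuplicated(flat)) {
    stop("alphabet groups overlap on: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "), call. = FALSE)
  }
  if (!setequal(flat, AA_STANDARD)) {
    missing <- setdiff(AA_STANDARD, flat)
    extra <- setdiff(flat, AA_STANDARD)
    stop("alphabet groups must partition the 20 standard letters exactly",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; not standard: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  symbols <- letters[seq_along(members)]
  lookup <- character(0)
  for (i in seq_along(members)) {
    lookup[members[[i]]] <- symbols[i]
  }
  rendering <- vapply(members, function(m) {
    if (length(m) == 1L) m else paste0("[", paste(m, collapse = ""), "]")
  }, character(1))
  names(rendering) <- symbols
  structure(list(name = name, groups = members, symbols = symbols,
                 lookup = lookup, rendering = rendering),
            class = "reduced_alphabet")
}

#' @export
print.reduced_alphabet <- function(x, ...) {
  cat("<reduced_alphabet> ", x$name, ": ",
      paste(x$rendering, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Retrieve a built-in reduced alphabet
#'
#' @param name one of `"enc7"`, `"enc8"`, `"enc10"` (7, 8 and 10
#'   physicochemical groups respectively).
#' @return a `reduced_alphabet`.
#' @examples
#' builtin_alphabet("enc7")
#' @export
builtin_alphabet <- function(name) {
  if (length(name) != 1L || !name %in% names(.BUILTIN_ALPHABETS)) {
    stop("unknown alphabet '", paste(name, collapse = ","), "'; valid names: ",
         paste(names(.BUILTIN_ALPHABETS), collapse = ", "), call. = FALSE)
  }
  reduced_alphabet(.BUILTIN_ALPHABETS[[name]], name = name)
}

#' Read a reduced alphabet from a config file
#'
#' Plain text, one group per line as concatenated letters (e.g. `AVIL`);
#' blank lines and lines starting with `#` are ignored. The groups must
#' partition the 20 standard letters.
#'
#' @param path file path.
#' @param name label; defaults to the file name.
#' @return a `reduced_alphabet`.
#' @examples
#' cfg <- system.file("extdata", "alphabet_enc7.txt", package = "gappedmotifs")
#' read_alphabet(cfg, name = "enc7")
#' @export
read_alphabet <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no groups found in ", path, call. = FALSE)
  reduced_alphabet(lines, name = name)
}

#' Recode sequences into a reduced alphabet
#'
#' Each residue is replaced by its group symbol; length is preserved. The
#' result is suitable for [count_matrix()] and [find_occurrences()].
#'
#' @param sequences character vector of residue strings over the 20 standard
#'   letters.
#' @param alphabet a `reduced_alphabet`.
#' @return character vector of recoded sequences (internal group symbols;
#'   see [render_motif()] for the external rendering).
#' @export
recode <- function(sequences, alphabet) {
  stopifnot(inherits(alphabet, "reduced_alphabet"))
  bad <- grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), sequences)
  if (any(bad)) {
    stop("sequence contains residues outside the 20 standard letters: ",
         sequences[bad][1], call. = FALSE)
  }
  old <- paste(names(alphabet$lookup), collapse = "")
  new <- paste(unname(alphabet$lookup), collapse = "")
  chartr(old, new, sequences)
}

#' Render internal group-symbol motif strings as bracketed letter sets
#'
#' @param motifs character vector of motif strings over an alphabet's
#'   internal group symbols (gaps as `_`).
#' @param alphabet the `reduced_alphabet` the symbols belong to.
#' @return character vector with each group symbol replaced by its bracketed
#'   (or bare, for singleton groups) rendering.
#' @export
render_motif <- function(motifs, alphabet) {
  stopifnot(inherits(alphabet, "reduced_alphabet"))
  vapply(strsplit(motifs, "", fixed = TRUE), function(ch) {
    paste0(ifelse(ch == "_", "_", alphabet$rendering[ch]), collapse = "")
  }, character(1))
}

#' Project a full-alphabet motif onto a reduced alphabet
#'
#' Every residue class of the motif is replaced by the union of the groups
#' its members belong to; any occurrence of the original motif is then also
#' an occurrence of the projected motif at the same start.
#'
#' @param pattern a `motif_pattern` or canonical motif string over the full
#'   alphabet.
#' @param alphabet a `reduced_alphabet`.
#' @return the projected motif's canonical (bracketed) string.
#' @export
project_motif <- function(pattern, alphabet) {
  pattern <- .as_pattern(pattern)
  syms <- lapply(pattern$classes, function(cl) unique(alphabet$lookup[cl]))
  if (any(lengths(syms) > 1L)) {
    stop("motif class straddles several groups of '", alphabet$name,
         "'; only within-group classes project", call. = FALSE)
  }
  rendered <- vapply(syms, function(s) alphabet$rendering[s], character(1))
  seps <- c(vapply(pattern$gaps, function(g) strrep("_", g), character(1)), "")
  paste0(paste0(rendered, seps), collapse = "")
}
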