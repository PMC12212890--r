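# Tokenization and the light suffix stemmer used by the cause classifier.
#
# The lexicon, the synthetic-corpus templates, and the entry descriptions are
# all passed through the same stem_text(), so matching is self-consistent:
# the stemmer does not need to agree with any external stemmer, only with
# itself. It implements the plural / -ed / -ing stripping portion of the
# classic Porter algorithm, which is what keyword matching on colloquial
# death phrases actually exercises.

cm_has_vowel <- function(w) grepl("[aeiouy]", w)

#' Stem a single lowercase token
#'
#' Light English suffix stemmer: strips plural endings (`sses` -> `ss`,
#' `ies` -> `i`, trailing `s`) and, when the remaining stem still contains a
#' vowel, the inflections `eed` -> `ee`, `-ed`, `-ing`. After `-ed`/`-ing`
#' removal, doubled final consonants (other than l, s, z) are singled.
#' Deterministic and idempotent on its own output for the lexicon vocabulary.
#'
#' @param w a character vector of lowercase tokens.
#' @return character vector of stems.
#' @keywords internal
cm_stem <- function(w) {
  vapply(w, function(x) {
    if (nchar(x) <= 2L) return(x)
    # step 1a: plurals
    if (grepl("sses$", x)) x <- sub("sses$", "ss", x)
    else if (grepl("ies$", x)) x <- sub("ies$", "i", x)
    else if (grepl("[^s]s$", x)) x <- sub("s$", "", x)
    # step 1b: -eed / -ed / -ing
    if (grepl("eed$", x)) {
      if (nchar(x) > 4L) x <- sub("eed$", "ee", x)
    } else if (grepl("ed$", x) && cm_has_vowel(sub("ed$", "", x))) {
      x <- sub("ed$", "", x)
      x <- cm_fix_after_strip(x)
    } else if (grepl("ing$", x) && cm_has_vowel(sub("ing$", "", x))) {
      x <- sub("ing$", "", x)
      x <- cm_fix_after_strip(x)
    }
    x
  }, character(1), USE.NAMES = FALSE)
}

# after -ed/-ing removal: restore -e for at/bl/iz endings, undouble consonants
cm_fix_after_strip <- function(x) {
  if (grepl("(at|bl|iz)$", x)) return(paste0(x, "e"))
  if (grepl("([^aeioulsz])\\1$", x)) return(sub("(.)\\1$", "\\1", x))
  x
}

#' Tokenize text into lowercase word tokens
#'
#' Lowercases, normalizes punctuation and entities ([normalize_text()]), and
#' splits on any non-alphanumeric character. Empty tokens are dropped.
#'
#' @param x character scalar.
#' @return character vector of tokens (possibly empty).
#' @export
cm_tokenize <- function(x) {
  x <- tolower(normalize_text(x))
  toks <- strsplit(x, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Reduce a death description to word stems
#'
#' The preprocessing applied to every entry description before lexicon
#' matching: lowercase, strip punctuation, tokenize, stem each token.
#'
#' @param description character scalar (free text; may be empty).
#' @return character vector of stems; `character(0)` for empty input.
#' @export
#' @examples
#' stem_text("Drowned while swimming")
#' stem_text("suffers a massive heart attack")
stem_text <- function(description) {
  if (is.null(description) || length(description) == 0L ||
      is.na(description) || !nzchar(trimws(description)))
    return(character(0))
  cm_stem(cm_tokenize(description))
}
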