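# Stem-lexicon classification of death descriptions into the 13 NVSS
# leading-cause categories (12 named causes + "other" fallback).

#' The 13 cause-of-death codes
#'
#' The 12 named NVSS 2021 leading causes (the union of the women's and men's
#' top-10 lists) plus the `other` fallback, in NVSS table order. This order
#' is also the tie-break priority when a description matches several causes.
#'
#' @return character vector of 13 codes.
#' @export
cause_codes <- function() {
  c("heart", "cancer", "covid19", "accidents", "cerebrovascular",
    "chronic_lower_respiratory", "alzheimer", "diabetes", "chronic_liver",
    "nephritis", "suicide", "hypertension", "other")
}

#' Load and validate a cause lexicon
#'
#' A lexicon is a JSON file with fields `version`, `stopwords`, and
#' `patterns` (cause code -> raw phrase list). Phrases are tokenized,
#' stopword-filtered, and stemmed at load into single-stem or stem-bigram
#' patterns. Load-time validation enforces: every named cause has at least
#' one pattern, `other` has none, and no stemmed pattern is claimed by two
#' causes (a configuration error, not a warning).
#'
#' @param path lexicon file; default is the packaged lexicon.
#' @return a `cm_lexicon`: `$version`, `$stop_stems`, `$unigrams` and
#'   `$bigrams` (named lists of pattern matrices per cause).
#' @export
load_lexicon <- function(path = path_extdata("cause_lexicon.json")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  codes <- cause_codes()
  pats <- raw$patterns
  unknown <- setdiff(names(pats), codes)
  if (length(unknown))
    stop("lexicon names unknown cause code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(pats$other %||% character(0)) > 0L)
    stop("'other' is the fallback and must carry no patterns", call. = FALSE)
  stop_stems <- unique(cm_stem(tolower(raw$stopwords %||% character(0))))
  uni <- list(); bi <- list()
  seen <- character(0)
  for (code in setdiff(codes, "other")) {
    phrases <- pats[[code]]
    if (is.null(phrases) || length(phrases) == 0L)
      stop("cause '", code, "' has no lexicon patterns", call. = FALSE)
    keys <- character(0); u <- character(0); b <- list()
    for (ph in phrases) {
      stems <- setdiff(stem_text(ph), stop_stems)
      if (length(stems) == 0L)
        stop("pattern '", ph, "' (", code, ") is empty after stopword removal",
             call. = FALSE)
      if (length(stems) > 2L)
        stop("pattern '", ph, "' (", code,
             ") has more than two content stems; only single stems and stem ",
             "bigrams are supported", call. = FALSE)
      keys <- c(keys, paste(stems, collapse = " "))
      if (length(stems) == 1L) u <- c(u, stems) else b <- c(b, list(stems))
    }
    keys <- unique(keys)
    dup <- intersect(keys, seen)
    if (length(dup))
      stop("pattern(s) claimed by two causes: ", paste(dup, collapse = ", "),
           call. = FALSE)
    seen <- c(seen, keys)
    uni[[code]] <- unique(u)
    bi[[code]] <- unique(b)
  }
  structure(list(version = raw$version %||% "unversioned",
                 stop_stems = stop_stems, unigrams = uni, bigrams = bi),
            class = "cm_lexicon")
}

#' @export
print.cm_lexicon <- function(x, ...) {
  n <- sum(lengths(x$unigrams)) + sum(lengths(x$bigrams))
  cat("<cm_lexicon> version", x$version, "-", n, "patterns over",
      length(x$unigrams), "named causes\n")
  invisible(x)
}

# which causes match a stem vector (bigrams on adjacent content stems)
matching_causes <- function(stems, lexicon) {
  content <- stems[!stems %in% lexicon$stop_stems]
  hits <- character(0)
  for (code in names(lexicon$unigrams)) {
    if (any(lexicon$unigrams[[code]] %in% content)) {
      hits <- c(hits, code); next
    }
    for (bg in lexicon$bigrams[[code]]) {
      idx <- which(content == bg[1])
      if (any(content[idx + 1L] == bg[2], na.rm = TRUE)) {
        hits <- c(hits, code); break
      }
    }
  }
  hits
}

#' Classify one stemmed description
#'
#' Returns the matching cause code; `other` when no pattern matches. When
#' several causes match, the NVSS-table priority order breaks the tie
#' (heart first) and the tie is logged.
#'
#' @param stems character vector of stems from [stem_text()].
#' @param lexicon a `cm_lexicon`.
#' @return a single cause code.
#' @export
#' @examples
#' lex <- load_lexicon()
#' classify_cause(stem_text("suffers a massive heart attack"), lex)
classify_cause <- function(stems, lexicon) {
  stopifnot(inherits(lexicon, "cm_lexicon"))
  hits <- matching_causes(stems, lexicon)
  if (length(hits) == 0L) return("other")
  if (length(hits) > 1L) {
    hits <- hits[order(match(hits, cause_codes()))]
    cm_log("classify_cause-tie", causes = hits, chosen = hits[1])
  }
  hits[1]
}

#' Classify every entry of a corpus
#'
#' @param corpus a `cm_corpus` (ingested and medium-filtered).
#' @param lexicon a `cm_lexicon`.
#' @return a `cm_cause_result`: `$counts` (named integer vector over the 13
#'   codes, summing to the corpus size), `$assignments` (per-entry audit
#'   data.frame with `entry_id`, `actor_name`, `cause`, `n_matches`),
#'   `$lexicon_version`.
#' @export
classify_corpus <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "cm_corpus"), inherits(lexicon, "cm_lexicon"))
  n <- nrow(corpus$entries)
  cause <- character(n); nm <- integer(n)
  for (i in seq_len(n)) {
    stems <- stem_text(corpus$entries$description[i])
    hits <- matching_causes(stems, lexicon)
    nm[i] <- length(hits)
    cause[i] <- if (length(hits) == 0L) "other" else
      hits[order(match(hits, cause_codes()))][1]
  }
  counts <- table(factor(cause, levels = cause_codes()))
  counts <- stats::setNames(as.integer(counts), cause_codes())
  cm_log("classify_cause", entries = n, multi_match = sum(nm > 1L),
         other = counts[["other"]])
  structure(list(
    counts = counts,
    assignments = data.frame(entry_id = seq_len(n),
                             actor_name = corpus$entries$actor_name,
                             cause = cause, n_matches = nm,
                             stringsAsFactors = FALSE),
    lexicon_version = lexicon$version), class = "cm_cause_result")
}
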