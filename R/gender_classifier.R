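# Name-dictionary gender classification of actors, with the consolidation
# rule: mostly_male -> man, mostly_female -> woman, androgynous/unknown
# excluded from gender-stratified statistics.

RAW_GENDER_LEVELS <- c("male", "female", "mostly_male", "mostly_female",
                       "androgynous", "unknown")
CONSOLIDATED_LEVELS <- c("man", "woman", "excluded")

HONORIFICS <- c("dr", "mr", "mrs", "ms", "miss", "sir", "dame", "lady",
                "lord", "prof", "professor", "rev", "capt", "captain",
                "sgt", "st")

#' Extract the first name from an actor name
#'
#' Strips parentheticals and leading honorifics, then returns the first
#' whitespace-delimited token. Diacritics are preserved. An actor name that
#' is empty after stripping yields `""` (which looks up as `unknown`).
#'
#' @param actor_name character vector of page-title actor names.
#' @return character vector of first names.
#' @export
#' @examples
#' extract_first_name("Dr. Ana María López")
extract_first_name <- function(actor_name) {
  vapply(actor_name, function(x) {
    x <- normalize_text(x)
    x <- gsub("\\([^)]*\\)", " ", x)
    toks <- strsplit(trimws(x), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    while (length(toks) > 0L &&
           tolower(gsub("\\.$", "", toks[1])) %in% HONORIFICS)
      toks <- toks[-1L]
    if (length(toks) == 0L) "" else toks[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Load a name-gender dictionary
#'
#' Two-column tab-separated text (`name`, `label`) with labels drawn from
#' `male, female, mostly_male, mostly_female, androgynous`; lines starting
#' with `#` are comments. Lookup is case-insensitive. The packaged default
#' is a small synthetic dictionary (see `inst/extdata/names_synthetic.tsv`);
#' any same-format dictionary, e.g. one exported from the gender-guesser
#' name database, can be substituted.
#'
#' @param path dictionary file.
#' @return a `cm_name_dict`: named character vector (normalized name ->
#'   raw label) with a `source` attribute.
#' @export
load_name_dictionary <- function(path = path_extdata("names_synthetic.tsv")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "label") %in% names(df)))
  bad <- !df$label %in% setdiff(RAW_GENDER_LEVELS, "unknown")
  if (any(bad))
    stop("invalid label(s) in name dictionary: ",
         paste(unique(df$label[bad]), collapse = ", "), call. = FALSE)
  key <- tolower(trimws(df$name))
  if (anyDuplicated(key))
    cm_log("name_dictionary", duplicate_names = sum(duplicated(key)))
  dict <- stats::setNames(df$label, key)[!duplicated(key)]
  structure(dict, source = basename(path), class = "cm_name_dict")
}

#' Look up the raw gender label for a first name
#'
#' Case-insensitive dictionary lookup; names absent from the dictionary
#' resolve to `unknown`. Hyphenated names are looked up in full first, then
#' by their first component.
#'
#' @param first_name character vector of first names.
#' @param name_dictionary a `cm_name_dict`.
#' @return character vector of raw labels (six-value vocabulary).
#' @export
lookup_gender <- function(first_name, name_dictionary) {
  stopifnot(inherits(name_dictionary, "cm_name_dict"))
  key <- tolower(trimws(first_name))
  lab <- unname(name_dictionary[key])
  retry <- is.na(lab) & grepl("-", key, fixed = TRUE)
  if (any(retry))
    lab[retry] <- unname(name_dictionary[sub("-.*$", "", key[retry])])
  lab[is.na(lab)] <- "unknown"
  lab
}

#' Consolidate raw gender labels
#'
#' `male`/`mostly_male` -> `man`; `female`/`mostly_female` -> `woman`;
#' `androgynous`/`unknown` -> `excluded`. Total function on the six-label
#' vocabulary.
#'
#' @param raw_label character vector of raw labels.
#' @return character vector over `man`, `woman`, `excluded`.
#' @export
consolidate <- function(raw_label) {
  bad <- !raw_label %in% RAW_GENDER_LEVELS
  if (any(bad))
    stop("invalid raw gender label(s): ",
         paste(unique(raw_label[bad]), collapse = ", "), call. = FALSE)
  map <- c(male = "man", mostly_male = "man",
           female = "woman", mostly_female = "woman",
           androgynous = "excluded", unknown = "excluded")
  unname(map[raw_label])
}

#' Tally raw labels before and after consolidation
#'
#' @param raw_labels one raw label per corpus entry.
#' @return a list with `before` (named counts over the six raw labels) and
#'   `after` (named counts over `man`, `woman`, `excluded`); both sum to
#'   `length(raw_labels)`.
#' @export
tally_genders <- function(raw_labels) {
  before <- table(factor(raw_labels, levels = RAW_GENDER_LEVELS))
  after <- table(factor(consolidate(raw_labels), levels = CONSOLIDATED_LEVELS))
  list(before = stats::setNames(as.integer(before), RAW_GENDER_LEVELS),
       after = stats::setNames(as.integer(after), CONSOLIDATED_LEVELS))
}

#' Classify the gender of every entry in a corpus
#'
#' Applies [extract_first_name()], [lookup_gender()] and [consolidate()] to
#' each entry and logs the excluded count.
#'
#' @param corpus a `cm_corpus`.
#' @param name_dictionary a `cm_name_dict`.
#' @return a `cm_gender_result`: `$assignments` (per-entry data.frame with
#'   `entry_id`, `actor_name`, `first_name`, `raw`, `consolidated`),
#'   `$tally` (see [tally_genders()]), `$dictionary_source`.
#' @export
classify_genders <- function(corpus, name_dictionary) {
  stopifnot(inherits(corpus, "cm_corpus"))
  first <- extract_first_name(corpus$entries$actor_name)
  raw <- lookup_gender(first, name_dictionary)
  cons <- consolidate(raw)
  tly <- tally_genders(raw)
  cm_log("classify_gender", entries = length(raw),
         excluded = tly$after[["excluded"]])
  structure(list(
    assignments = data.frame(entry_id = seq_along(raw),
                             actor_name = corpus$entries$actor_name,
                             first_name = first, raw = raw,
                             consolidated = cons, stringsAsFactors = FALSE),
    tally = tly,
    dictionary_source = attr(name_dictionary, "source")),
    class = "cm_gender_result")
}
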