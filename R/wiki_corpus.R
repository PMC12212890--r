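# Ingestion of MediaWiki-style XML dumps (and the CSV interchange format)
# into a corpus of per-actor death entries.

MEDIA_LEVELS <- c("film", "television", "video_game", "other_media", "unknown")

ENTRY_COLS <- c("actor_name", "film_title", "year", "medium", "description")

new_corpus <- function(entries, source_id = "", extraction_date = Sys.Date(),
                       warnings = character(0)) {
  stopifnot(is.data.frame(entries), all(ENTRY_COLS %in% names(entries)))
  entries <- entries[, ENTRY_COLS, drop = FALSE]
  rownames(entries) <- NULL
  structure(
    list(entries = entries, source_id = source_id,
         extraction_date = as.Date(extraction_date), warnings = warnings),
    class = "cm_corpus")
}

#' @export
print.cm_corpus <- function(x, ...) {
  cat("<cm_corpus> ", nrow(x$entries), " entries from '", x$source_id,
      "' (", format(x$extraction_date), ")\n", sep = "")
  tab <- table(factor(x$entries$medium, levels = MEDIA_LEVELS))
  cat("  by medium:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (length(x$warnings))
    cat("  ", length(x$warnings), "parse warning(s)\n")
  invisible(x)
}

#' Number of entries in a corpus
#' @param x a `cm_corpus`.
#' @param ... ignored.
#' @export
length.cm_corpus <- function(x) nrow(x$entries)

# -- entry grammar ------------------------------------------------------------
# One wiki list item (a line starting with "*" or "#") is one death entry.
# film_title and year come from the first parenthesized 4-digit year and the
# preceding italic ''...'' or link [[...]] span; if neither markup is present,
# the run of capitalized words immediately before the parenthesis is used.
# Everything else is the description.
parse_entry_line <- function(line, actor_name) {
  txt <- normalize_text(sub("^[*#:]+\\s*", "", line))
  if (!nzchar(txt)) return(NULL)
  m <- regexpr("\\((1[89][0-9]{2}|20[0-9]{2})\\)", txt)
  year <- NA_integer_
  film_title <- NA_character_
  desc <- txt
  if (m > 0L) {
    year <- as.integer(substr(txt, m + 1L, m + 4L))
    before <- substr(txt, 1L, m - 1L)
    after <- substr(txt, m + attr(m, "match.length"), nchar(txt))
    tm <- regexpr("''[^']+''\\s*$|\\[\\[[^]]+\\]\\]\\s*$", before)
    if (tm > 0L) {
      span <- trimws(substr(before, tm, nchar(before)))
      film_title <- gsub("^''|''$|^\\[\\[|\\]\\]$", "", span)
      film_title <- sub("\\|.*$", "", film_title)
      before <- substr(before, 1L, tm - 1L)
    } else {
      # maximal run of capitalized/numeric words directly before "(year)"
      tm <- regexpr("((?:[A-Z][A-Za-z0-9'&.-]*|[0-9]+)(?:\\s+(?:[A-Z][A-Za-z0-9'&.-]*|[0-9]+))*)\\s*$",
                    before)
      if (tm > 0L && attr(tm, "match.length") > 0L) {
        film_title <- trimws(substr(before, tm, nchar(before)))
        before <- substr(before, 1L, tm - 1L)
      }
    }
    desc <- normalize_text(paste(before, after))
    # the title span may be the whole line ("Film X (1972)" with no prose)
    if (!nzchar(desc)) desc <- txt
  }
  desc <- sub("[-,;:. ]+$", "", desc)
  if (!nzchar(desc)) return(NULL)
  data.frame(actor_name = actor_name, film_title = film_title, year = year,
             medium = NA_character_, description = desc,
             stringsAsFactors = FALSE)
}

# Medium detection: page category tags when present, else keyword evidence in
# title/description; entries with no evidence are treated as film.
detect_medium <- function(film_title, description, page_categories = character(0)) {
  cats <- tolower(page_categories)
  if (any(grepl("television|tv deaths", cats))) return("television")
  if (any(grepl("video game", cats))) return("video_game")
  if (is.na(film_title)) film_title <- ""
  blob <- tolower(paste(film_title, description))
  if (grepl("\\bepisode\\b|\\bseason\\b|\\btv series\\b", blob)) return("television")
  if (grepl("video game", blob)) return("video_game")
  "film"
}

#' Parse a MediaWiki XML dump (or entries CSV) into a corpus
#'
#' XML input must follow the `<mediawiki><page><title>...<revision><text>`
#' export schema; each wiki list item inside a page's text becomes one
#' [DeathEntry][parse_dump] row with `actor_name` taken from the page title.
#' CSV input must carry the canonical header
#' `actor_name,film_title,year,medium,description`. Pages whose text contains
#' no list items yield zero entries; pages that cannot be processed are
#' skipped with a logged warning, never dropped silently.
#'
#' @param xml_source path to a `.xml` dump or `.csv` entries file, or a
#'   character scalar holding raw XML (must start with `<`).
#' @param source_id identifier recorded on the corpus; defaults to the file
#'   name.
#' @return a `cm_corpus`: `$entries` (data.frame with columns `actor_name`,
#'   `film_title`, `year`, `medium`, `description`), `$source_id`,
#'   `$extraction_date`, `$warnings`.
#' @export
parse_dump <- function(xml_source, source_id = NULL) {
  is_path <- length(xml_source) == 1L && !grepl("^\\s*<", xml_source) &&
    file.exists(xml_source)
  if (is_path && grepl("\\.csv$", xml_source, ignore.case = TRUE))
    return(read_entries_csv(xml_source,
                            source_id = source_id %||% basename(xml_source)))
  doc <- tryCatch(
    if (is_path) xml2::read_xml(xml_source) else xml2::read_xml(xml_source),
    error = function(e) stop("malformed XML: ", conditionMessage(e),
                             call. = FALSE))
  xml2::xml_ns_strip(doc)
  pages <- xml2::xml_find_all(doc, ".//page")
  warnings <- character(0)
  rows <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    title <- xml2::xml_text(xml2::xml_find_first(pages[[i]], "./title"))
    text <- xml2::xml_text(xml2::xml_find_first(pages[[i]], ".//revision/text"))
    if (is.na(title) || !nzchar(title)) {
      warnings <- c(warnings, sprintf("page %d skipped: missing title", i))
      next
    }
    if (is.na(text)) {
      warnings <- c(warnings,
                    sprintf("page '%s' skipped: no revision text", title))
      next
    }
    cats <- regmatches(text,
                       gregexpr("\\[\\[Category:[^]]+\\]\\]", text))[[1]]
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    items <- lines[grepl("^[*#]", lines)]
    if (length(items) == 0L) next
    parsed <- lapply(items, parse_entry_line, actor_name = normalize_text(title))
    parsed <- parsed[!vapply(parsed, is.null, logical(1))]
    if (length(parsed) == 0L) {
      warnings <- c(warnings,
                    sprintf("page '%s' skipped: no parsable entries", title))
      next
    }
    df <- do.call(rbind, parsed)
    df$medium <- mapply(detect_medium, df$film_title, df$description,
                        MoreArgs = list(page_categories = cats))
    rows[[i]] <- df
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  entries <- if (length(rows)) do.call(rbind, rows) else
    empty_entries()
  for (w in warnings) cm_log("ingest-warning", detail = w)
  cm_log("ingest", pages = length(pages), entries = nrow(entries),
         warnings = length(warnings))
  new_corpus(entries,
             source_id = source_id %||%
               (if (is_path) basename(xml_source) else "inline-xml"),
             warnings = warnings)
}

empty_entries <- function() {
  data.frame(actor_name = character(0), film_title = character(0),
             year = integer(0), medium = character(0),
             description = character(0), stringsAsFactors = FALSE)
}

#' Read / write the canonical entries CSV
#'
#' The interchange format used between pipeline stages: a CSV with header
#' `actor_name,film_title,year,medium,description`. Writing then reading a
#' corpus round-trips it exactly (up to the source id).
#'
#' @param path file path.
#' @param source_id identifier recorded on the corpus.
#' @return `read_entries_csv`: a `cm_corpus`; `write_entries_csv`: the path,
#'   invisibly.
#' @export
read_entries_csv <- function(path, source_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(actor_name = "character",
                                       film_title = "character",
                                       year = "integer",
                                       medium = "character",
                                       description = "character"))
  missing <- setdiff(ENTRY_COLS, names(df))
  if (length(missing))
    stop("entries CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$medium[is.na(df$medium) | !nzchar(df$medium)] <- "unknown"
  bad <- !df$medium %in% MEDIA_LEVELS
  if (any(bad))
    stop("unknown medium label(s): ",
         paste(unique(df$medium[bad]), collapse = ", "), call. = FALSE)
  new_corpus(df[, ENTRY_COLS], source_id = source_id)
}

#' @param corpus a `cm_corpus`.
#' @rdname read_entries_csv
#' @export
write_entries_csv <- function(corpus, path) {
  stopifnot(inherits(corpus, "cm_corpus"))
  utils::write.csv(corpus$entries, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a corpus to selected media
#'
#' The analysis restricts to film deaths; television and video-game entries
#' are excluded. Order is preserved and the removed count is logged.
#'
#' @param corpus a `cm_corpus`.
#' @param allowed_media non-empty character vector of medium labels.
#' @return filtered `cm_corpus`.
#' @export
filter_medium <- function(corpus, allowed_media = "film") {
  stopifnot(inherits(corpus, "cm_corpus"))
  if (length(allowed_media) == 0L || !all(allowed_media %in% MEDIA_LEVELS))
    stop("`allowed_media` must be a non-empty subset of: ",
         paste(MEDIA_LEVELS, collapse = ", "), call. = FALSE)
  keep <- corpus$entries$medium %in% allowed_media
  cm_log("filter_medium", kept = sum(keep), removed = sum(!keep))
  new_corpus(corpus$entries[keep, , drop = FALSE],
             source_id = corpus$source_id,
             extraction_date = corpus$extraction_date,
             warnings = corpus$warnings)
}

#' Empirical year percentiles of a corpus
#'
#' Nearest-rank (inverse empirical CDF, `quantile type = 1`) percentiles of
#' the entry years, so reported years are always observed years. Entries
#' with a missing year are excluded with a logged count.
#'
#' @param corpus a `cm_corpus`.
#' @param probs probabilities; 0 and 1 return the min and max.
#' @return data.frame with columns `percentile` and `year`.
#' @export
year_percentiles <- function(corpus, probs = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(inherits(corpus, "cm_corpus"))
  years <- corpus$entries$year
  miss <- is.na(years)
  if (any(miss)) cm_log("year_percentiles", missing_year = sum(miss))
  years <- years[!miss]
  if (length(years) == 0L)
    stop("no entries with a year", call. = FALSE)
  q <- stats::quantile(years, probs = probs, type = 1, names = FALSE)
  data.frame(percentile = probs, year = as.integer(q))
}

#' JSON ingest report
#'
#' Counts by medium plus any parse warnings, written as JSON.
#'
#' @param corpus a `cm_corpus`.
#' @param path output path; `NULL` returns the report list.
#' @return the report list, invisibly when written.
#' @export
ingest_report <- function(corpus, path = NULL) {
  stopifnot(inherits(corpus, "cm_corpus"))
  tab <- table(factor(corpus$entries$medium, levels = MEDIA_LEVELS))
  rep <- list(source_id = corpus$source_id,
              extraction_date = format(corpus$extraction_date),
              n_entries = nrow(corpus$entries),
              by_medium = as.list(stats::setNames(as.integer(tab), names(tab))),
              warnings = corpus$warnings)
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(rep)
}
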