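# Synthetic Cinemorgue-like corpus generator with planted cause and gender
# structure, used to test every pipeline stage without the real dump.

# Per-cause description templates. Each template embeds exactly one lexicon
# pattern ({p}); the filler vocabulary deliberately avoids every lexicon
# stem so truth tables are exact (classifier recall is 1 by construction on
# template-only corpora).
SYNTH_TEMPLATES <- c(
  "Succumbs to {p} near the end",
  "Perishes from {p} midway through the story",
  "Passes away off screen as the result of {p}",
  "Expires slowly, victim of {p}, mourned later",
  "Meets a grim demise, undone when {p} strikes")

# Names deliberately absent from the packaged dictionary -> lookup unknown.
SYNTH_UNKNOWN_NAMES <- c("Zephrine", "Quorra", "Vexley", "Thandrel",
                         "Ilyovar", "Nyxette", "Orvalet", "Brindlyn")

SYNTH_SURNAMES <- c("Hartwell", "Okafor", "Ramirez", "Silva", "Novak",
                    "Tanaka", "Lindqvist", "Moreau", "Petrov", "Nguyen",
                    "Adeyemi", "Kowalski", "Rossi", "Fernsby", "Ashdown",
                    "Bell", "Crane", "Duval", "Eastwood", "Forsythe")

#' Generator configuration for synthetic corpora
#'
#' Defaults describe a corpus with the published film-side character: cause
#' mixture with the printed per-cause film masses (heart 648,
#' cerebrovascular 72, suicide 2,382, accidents 1,250 per 68,535 deaths,
#' remainder mostly `other`), per-cause probability of a man dying equal to
#' the printed film proportions (0.736, 0.694, 0.603, 0.612; 0.709
#' elsewhere, the corpus-wide value), 13% ambiguous names, years uniform on
#' 1895-2023, film-only media.
#'
#' @param n_entries number of entries to generate.
#' @param cause_mixture named probabilities over cause codes (must sum to 1).
#' @param gender_mixture_by_cause named per-cause probability of `man`;
#'   causes absent from the vector fall back to `default_p_man`.
#' @param default_p_man fallback probability of `man`.
#' @param ambiguous_name_fraction probability an entry receives an
#'   androgynous/unknown-labeled name (and is later excluded).
#' @param media_mixture named probabilities over medium labels.
#' @param year_range integer `c(min, max)`.
#' @param seed integer seed driving all sampling.
#' @return a `cm_generator_config` list.
#' @export
generator_config <- function(n_entries = 1000,
                             cause_mixture = c(heart = 648, cerebrovascular = 72,
                                               suicide = 2382, accidents = 1250,
                                               cancer = 500,
                                               other = 68535 - 648 - 72 - 2382 -
                                                 1250 - 500) / 68535,
                             gender_mixture_by_cause = c(heart = 0.736,
                                                         cerebrovascular = 0.694,
                                                         suicide = 0.603,
                                                         accidents = 0.612),
                             default_p_man = 0.709,
                             ambiguous_name_fraction = 0.13,
                             media_mixture = c(film = 1),
                             year_range = c(1895L, 2023L),
                             seed = 1L) {
  stopifnot_scalar_count(n_entries, "n_entries")
  if (abs(sum(cause_mixture) - 1) > 1e-8 || any(cause_mixture < 0) ||
      any(cause_mixture > 1))
    stop("`cause_mixture` must be probabilities summing to 1", call. = FALSE)
  bad <- setdiff(names(cause_mixture), cause_codes())
  if (length(bad))
    stop("unknown cause(s) in mixture: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (abs(sum(media_mixture) - 1) > 1e-8)
    stop("`media_mixture` must sum to 1", call. = FALSE)
  if (ambiguous_name_fraction < 0 || ambiguous_name_fraction > 1)
    stop("`ambiguous_name_fraction` must be in [0, 1]", call. = FALSE)
  structure(list(n_entries = as.integer(n_entries),
                 cause_mixture = cause_mixture,
                 gender_mixture_by_cause = gender_mixture_by_cause,
                 default_p_man = default_p_man,
                 ambiguous_name_fraction = ambiguous_name_fraction,
                 media_mixture = media_mixture,
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "cm_generator_config")
}

# raw lexicon phrases per cause (templates embed raw phrases, which then
# stem to lexicon patterns)
lexicon_raw_phrases <- function(lexicon_path = path_extdata("cause_lexicon.json")) {
  raw <- jsonlite::read_json(lexicon_path, simplifyVector = TRUE)
  raw$patterns
}

name_pools <- function(name_dictionary) {
  stopifnot(inherits(name_dictionary, "cm_name_dict"))
  nm <- names(name_dictionary)
  cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  list(man = cap(nm[name_dictionary %in% c("male", "mostly_male")]),
       woman = cap(nm[name_dictionary %in% c("female", "mostly_female")]),
       ambiguous = c(cap(nm[name_dictionary == "androgynous"]),
                     SYNTH_UNKNOWN_NAMES))
}

#' Generate a synthetic corpus with a truth table
#'
#' Each entry samples a cause from the cause mixture, a gender from the
#' per-cause gender mixture, an actor name from the matching name pool
#' (ambiguous pool with probability `ambiguous_name_fraction`), a year
#' uniform in the year range, a medium from the media mixture, and a
#' description template embedding one lexicon phrase for the sampled cause.
#' Identical seeds give identical corpora; the seed is recorded on the
#' truth table.
#'
#' @param config a `cm_generator_config`.
#' @param lexicon_path path to the lexicon JSON supplying raw phrases.
#' @param name_dictionary a `cm_name_dict` supplying the name pools.
#' @return list with `corpus` (`cm_corpus`), `truth` (data.frame:
#'   `entry_id`, `actor_name`, `cause`, `gender`, `ambiguous_name`,
#'   `medium`, `year`), and `xml` (the corpus as a MediaWiki dump string,
#'   accepted unchanged by [parse_dump()]).
#' @export
generate_corpus <- function(config = generator_config(),
                            lexicon_path = path_extdata("cause_lexicon.json"),
                            name_dictionary = load_name_dictionary()) {
  stopifnot(inherits(config, "cm_generator_config"))
  phrases <- lexicon_raw_phrases(lexicon_path)
  pools <- name_pools(name_dictionary)
  for (code in names(config$cause_mixture)) {
    if (config$cause_mixture[[code]] > 0 && code != "other" &&
        length(phrases[[code]] %||% character(0)) == 0L)
      stop("cause '", code, "' in mixture has no lexicon phrases",
           call. = FALSE)
  }
  n <- config$n_entries
  set.seed(config$seed)
  if (n == 0L) {
    return(list(corpus = new_corpus(empty_entries(), source_id = "synthetic"),
                truth = data.frame(entry_id = integer(0),
                                   actor_name = character(0),
                                   cause = character(0),
                                   gender = character(0),
                                   ambiguous_name = logical(0),
                                   medium = character(0),
                                   year = integer(0)),
                xml = synth_xml(empty_entries(), config$seed)))
  }
  cause <- sample(names(config$cause_mixture), n, replace = TRUE,
                  prob = config$cause_mixture)
  p_man <- config$gender_mixture_by_cause[cause]
  p_man[is.na(p_man)] <- config$default_p_man
  gender <- ifelse(stats::runif(n) < p_man, "man", "woman")
  ambiguous <- stats::runif(n) < config$ambiguous_name_fraction
  first <- character(n)
  for (i in seq_len(n)) {
    pool <- if (ambiguous[i]) pools$ambiguous else pools[[gender[i]]]
    first[i] <- sample(pool, 1L)
  }
  actor <- paste(first, sample(SYNTH_SURNAMES, n, replace = TRUE))
  year <- sample(seq(config$year_range[1], config$year_range[2]), n,
                 replace = TRUE)
  medium <- sample(names(config$media_mixture), n, replace = TRUE,
                   prob = config$media_mixture)
  desc <- character(n)
  for (i in seq_len(n)) {
    ph <- if (cause[i] == "other") "an unnamed calamity" else
      sample(phrases[[cause[i]]], 1L)
    tpl <- sample(SYNTH_TEMPLATES, 1L)
    d <- sub("{p}", ph, tpl, fixed = TRUE)
    if (medium[i] == "television") d <- paste(d, "in a late season episode")
    if (medium[i] == "video_game") d <- paste(d, "in a video game level")
    desc[i] <- d
  }
  film <- paste("The", sample(c("Silent", "Crimson", "Endless", "Hollow",
                                "Gilded", "Broken", "Winter", "Velvet"),
                              n, replace = TRUE),
                sample(c("Harbor", "Letter", "Garden", "Mirror", "Parade",
                         "Voyage", "Orchard", "Signal"), n, replace = TRUE))
  entries <- data.frame(actor_name = actor, film_title = film,
                        year = as.integer(year), medium = medium,
                        description = desc, stringsAsFactors = FALSE)
  truth <- data.frame(entry_id = seq_len(n), actor_name = actor,
                      cause = cause, gender = gender,
                      ambiguous_name = ambiguous, medium = medium,
                      year = as.integer(year), stringsAsFactors = FALSE)
  list(corpus = new_corpus(entries, source_id = sprintf("synthetic-seed%d",
                                                        config$seed)),
       truth = truth,
       xml = synth_xml(entries, config$seed))
}

# serialize entries as a MediaWiki export document, one page per actor,
# one list item per entry
synth_xml <- function(entries, seed) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  pages <- character(0)
  if (nrow(entries)) {
    by_actor <- split(entries, entries$actor_name)
    # deterministic page order
    by_actor <- by_actor[order(names(by_actor))]
    pages <- vapply(by_actor, function(df) {
      items <- sprintf("*%s in ''%s'' (%d).", df$description, df$film_title,
                       df$year)
      paste0("  <page>\n    <title>", esc(df$actor_name[1]),
             "</title>\n    <revision>\n      <text>",
             esc(paste(items, collapse = "\n")),
             "</text>\n    </revision>\n  </page>")
    }, character(1))
  }
  paste0("<mediawiki>\n  <!-- synthetic corpus, seed ", seed, " -->\n",
         paste(pages, collapse = "\n"), "\n</mediawiki>\n")
}

#' Write a synthetic fixture set to disk
#'
#' XML dump, canonical entries CSV, and truth-table CSV (with the seed in a
#' header comment).
#'
#' @param sim output of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the truth-table header.
#' @return named vector of the three file paths, invisibly.
#' @export
write_synthetic_fixture <- function(sim, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xml_path <- file.path(dir, "synthetic_dump.xml")
  csv_path <- file.path(dir, "entries.csv")
  truth_path <- file.path(dir, "truth.csv")
  writeLines(sim$xml, xml_path, sep = "")
  write_entries_csv(sim$corpus, csv_path)
  con <- file(truth_path, "w")
  writeLines(sprintf("# synthetic truth table, seed=%s", seed), con)
  utils::write.csv(sim$truth, con, row.names = FALSE)
  close(con)
  invisible(c(xml = xml_path, entries = csv_path, truth = truth_path))
}

#' Score pipeline output against the generator truth table
#'
#' Per-cause recall and precision of the cause classifier, gender agreement
#' on non-excluded entries, and the excluded fraction.
#'
#' @param truth truth data.frame from [generate_corpus()].
#' @param cause_result a `cm_cause_result` from [classify_corpus()].
#' @param gender_result a `cm_gender_result` from [classify_genders()].
#' @return list with `cause` (data.frame: `cause`, `n_true`, `recall`,
#'   `precision`), `gender_agreement`, `excluded_fraction`.
#' @export
evaluate_recovery <- function(truth, cause_result, gender_result) {
  stopifnot(inherits(cause_result, "cm_cause_result"),
            inherits(gender_result, "cm_gender_result"))
  a <- cause_result$assignments
  g <- gender_result$assignments
  if (nrow(a) != nrow(truth) || nrow(g) != nrow(truth) ||
      !all(a$entry_id == truth$entry_id))
    stop("truth table and pipeline output are not aligned by entry id",
         call. = FALSE)
  per_cause <- lapply(sort(unique(truth$cause)), function(code) {
    tp <- sum(truth$cause == code & a$cause == code)
    data.frame(cause = code, n_true = sum(truth$cause == code),
               recall = tp / max(sum(truth$cause == code), 1L),
               precision = if (sum(a$cause == code) > 0)
                 tp / sum(a$cause == code) else NA_real_,
               stringsAsFactors = FALSE)
  })
  kept <- g$consolidated != "excluded"
  agree <- if (any(kept))
    mean(g$consolidated[kept] == truth$gender[kept]) else NA_real_
  list(cause = do.call(rbind, per_cause),
       gender_agreement = agree,
       excluded_fraction = mean(!kept))
}
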