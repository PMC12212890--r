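# Fixture builders shared across the suite. Everything is constructed in
# code at test time; no binary fixtures.

# a MediaWiki export string from a named list: page title -> entry lines
make_dump <- function(pages) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- vapply(names(pages), function(title) {
    paste0("  <page>\n    <title>", esc(title), "</title>\n",
           "    <revision>\n      <text>",
           esc(paste(pages[[title]], collapse = "\n")),
           "</text>\n    </revision>\n  </page>")
  }, character(1))
  paste0("<mediawiki>\n", paste(body, collapse = "\n"), "\n</mediawiki>")
}

# a tiny two-cause lexicon written to a temp JSON file
make_fixture_lexicon <- function(patterns = list(
                                   heart = c("heart attack"),
                                   accidents = c("falls", "drowns")),
                                 stopwords = c("a", "the", "of", "from"),
                                 version = "test-lex-1") {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  jsonlite::write_json(list(version = version, stopwords = stopwords,
                            patterns = patterns),
                       path, auto_unbox = TRUE)
  path
}

# fill a pattern list so load_lexicon's every-cause-covered rule passes
full_patterns <- function(override = list()) {
  base <- list(heart = "heart attack", cancer = "cancer", covid19 = "covid",
               accidents = "drowns", cerebrovascular = "stroke",
               chronic_lower_respiratory = "emphysema",
               alzheimer = "dementia", diabetes = "diabetes",
               chronic_liver = "cirrhosis", nephritis = "nephritis",
               suicide = "suicide", hypertension = "hypertension",
               other = character(0))
  base[names(override)] <- override
  base
}

make_fixture_dict <- function(entries = c(maria = "female", james = "male",
                                          alex = "androgynous",
                                          leslie = "mostly_male",
                                          dana = "mostly_female")) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("name\tlabel",
               paste(names(entries), entries, sep = "\t")), path)
  structure(path, class = "character")
}

make_corpus <- function(actor_name, description,
                        film_title = "Some Film", year = 2000L,
                        medium = "film") {
  n <- max(length(actor_name), length(description))
  df <- data.frame(actor_name = rep_len(actor_name, n),
                   film_title = rep_len(film_title, n),
                   year = rep_len(as.integer(year), n),
                   medium = rep_len(medium, n),
                   description = rep_len(description, n),
                   stringsAsFactors = FALSE)
  cinemort:::new_corpus(df, source_id = "fixture")
}

# brute-force two-cell goodness-of-fit oracle, kept deliberately independent
# of gender_gof_chisq's implementation path
oracle_gof <- function(o1, o2, p) {
  n <- o1 + o2
  e1 <- n * p
  e2 <- n * (1 - p)
  (o1 - e1)^2 / e1 + (o2 - e2)^2 / e2
}
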