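test_that("parse_dump handles an empty page list", {
  corpus <- parse_dump("<mediawiki></mediawiki>")
  expect_s3_class(corpus, "cm_corpus")
  expect_identical(length(corpus), 0L)
})

test_that("parse_dump yields one entry per list item, actor from page title", {
  dump <- make_dump(list(
    "Anna Stone" = c("*Perishes from a stroke in ''Alpha'' (1990).",
                     "*Drowns at sea in ''Beta'' (1995)."),
    "Ben Okafor" = c("*Succumbs to cancer in ''Gamma'' (2001).",
                     "*Expires after an accident in ''Delta'' (2003)."),
    "Cleo Marsh" = c("*Dies of emphysema in ''Epsilon'' (2010).",
                     "*Killed by a rival in ''Zeta'' (2012).")))
  corpus <- parse_dump(dump)
  expect_identical(length(corpus), 6L)
  expect_setequal(unique(corpus$entries$actor_name),
                  c("Anna Stone", "Ben Okafor", "Cleo Marsh"))
  expect_identical(sum(corpus$entries$actor_name == "Anna Stone"), 2L)
})

test_that("entry grammar extracts year, title and description", {
  dump <- make_dump(list(
    "Jane Doe" = c("*Shot by the sheriff in Film X (1972).",
                   "*Perishes from a stroke in ''The Mirror'' (1999).",
                   "*Drowns saving a child in [[River Song|The River]] (1984).",
                   "*No year or film mentioned at all.")))
  e <- parse_dump(dump)$entries
  expect_identical(e$year[1:3], c(1972L, 1999L, 1984L))
  expect_identical(e$film_title[1:3], c("Film X", "The Mirror", "River Song"))
  expect_true(is.na(e$year[4]))
  expect_true(all(nzchar(trimws(e$description))))
  expect_match(e$description[1], "Shot by the sheriff")
})

test_that("medium detection uses categories then keywords, default film", {
  dump <- make_dump(list(
    "Tv Actor" = c("*Dies in a season finale episode (2001).",
                   "[[Category:Deaths]]"),
    "Game Actor" = c("*Falls in a video game level (2015)."),
    "Film Actor" = c("*Dies quietly at home (1999)."),
    "Cat Actor" = c("*Dies on set (2005).", "[[Category:Television Deaths]]")))
  e <- parse_dump(dump)$entries
  med <- setNames(e$medium, e$actor_name)
  expect_identical(unname(med["Tv Actor"]), "television")
  expect_identical(unname(med["Game Actor"]), "video_game")
  expect_identical(unname(med["Film Actor"]), "film")
  expect_identical(unname(med["Cat Actor"]), "television")
})

test_that("malformed XML is a fatal parse error; entry-less pages logged", {
  expect_error(parse_dump("<mediawiki><page>"), "malformed XML")
  dump <- make_dump(list("Prose Page" = "Just prose, no list items.",
                         "Real Page" = "*Dies bravely in ''Eta'' (2000)."))
  expect_message(corpus <- parse_dump(dump), "ingest")
  expect_identical(length(corpus), 1L)
})

test_that("parse_dump is deterministic and idempotent on the same bytes", {
  dump <- make_dump(list("A B" = "*Perishes from a stroke in ''X'' (1990)."))
  c1 <- suppressMessages(parse_dump(dump))
  c2 <- suppressMessages(parse_dump(dump))
  expect_identical(c1$entries, c2$entries)
})

test_that("filter_medium keeps allowed media, preserves order, logs removal", {
  corpus <- make_corpus(actor_name = paste("Actor", 1:8),
                        description = "Dies on screen",
                        medium = c(rep("film", 5), rep("television", 3)))
  expect_message(kept <- filter_medium(corpus, "film"), "removed=3")
  expect_identical(length(kept), 5L)
  expect_identical(kept$entries$actor_name, paste("Actor", 1:5))
  # identity on all media
  all_media <- cinemort:::MEDIA_LEVELS
  expect_identical(filter_medium(corpus, all_media)$entries, corpus$entries)
  # empty corpus stays empty
  empty <- make_corpus(character(0), character(0))
  expect_identical(length(filter_medium(empty, "film")), 0L)
  # invalid arguments
  expect_error(filter_medium(corpus, character(0)), "non-empty")
  expect_error(filter_medium(corpus, "radio"), "non-empty subset")
})

test_that("sequential medium filters compose like intersection", {
  set.seed(11)
  corpus <- make_corpus(actor_name = paste("Actor", 1:40),
                        description = "Dies",
                        medium = sample(cinemort:::MEDIA_LEVELS, 40,
                                        replace = TRUE))
  a <- c("film", "television", "video_game")
  b <- c("television", "video_game", "other_media")
  lhs <- filter_medium(filter_medium(corpus, a), b)
  rhs <- filter_medium(corpus, intersect(a, b))
  expect_identical(lhs$entries, rhs$entries)
})

test_that("year_percentiles uses nearest-rank and excludes missing years", {
  const <- make_corpus(paste("A", 1:7), "Dies", year = 2000L)
  p <- year_percentiles(const)
  expect_true(all(p$year == 2000L))
  uni <- make_corpus(paste("A", 1:100), "Dies", year = 1:100 + 1900L)
  med <- year_percentiles(uni)$year[3] - 1900L
  expect_true(med %in% c(50L, 51L))  # nearest-rank gives 50
  expect_identical(year_percentiles(uni)$year[c(1, 5)], c(1901L, 2000L))
  # missing years excluded with a log line
  mix <- make_corpus(paste("A", 1:4), "Dies",
                     year = c(1990L, NA, 2000L, NA))
  expect_message(p2 <- year_percentiles(mix), "missing_year=2")
  expect_identical(p2$year[c(1, 5)], c(1990L, 2000L))
  none <- make_corpus("A", "Dies", year = NA_integer_)
  expect_error(suppressMessages(year_percentiles(none)), "no entries")
})

test_that("entries CSV round-trips a corpus exactly", {
  corpus <- make_corpus(
    actor_name = c("Ana María López", "Jean-Luc Picard", "O'Brien"),
    description = c("Dies of a \"broken\" heart, twice",
                    "Perishes, quietly; alone", "Falls far"),
    film_title = c("Café Noir", "Ship's Log", "The Fall"),
    year = c(1950L, 1987L, NA), medium = c("film", "television", "unknown"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_entries_csv(corpus, path)
  back <- read_entries_csv(path)
  expect_identical(back$entries, corpus$entries)
  # parse_dump dispatches on the .csv extension too
  back2 <- parse_dump(path)
  expect_identical(back2$entries, corpus$entries)
})

test_that("ingest_report counts by medium and carries warnings", {
  corpus <- make_corpus(paste("A", 1:3), "Dies",
                        medium = c("film", "film", "television"))
  rep <- ingest_report(corpus)
  expect_identical(rep$by_medium$film, 2L)
  expect_identical(rep$by_medium$television, 1L)
  expect_identical(rep$n_entries, 3L)
  path <- withr::local_tempfile(fileext = ".json")
  ingest_report(corpus, path)
  expect_identical(jsonlite::read_json(path)$n_entries, 3L)
})
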