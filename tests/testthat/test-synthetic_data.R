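test_that("generator config validates its mixtures", {
  expect_error(generator_config(cause_mixture = c(heart = 0.5)),
               "summing to 1")
  expect_error(generator_config(cause_mixture = c(smallpox = 1)),
               "unknown cause")
  expect_error(generator_config(ambiguous_name_fraction = 1.2),
               "\\[0, 1\\]")
  expect_error(generator_config(media_mixture = c(film = 0.5)),
               "sum to 1")
  cfg <- generator_config(n_entries = 10)
  expect_s3_class(cfg, "cm_generator_config")
  expect_equal(sum(cfg$cause_mixture), 1)
})

test_that("n = 0 yields an empty corpus and truth table", {
  sim <- generate_corpus(generator_config(n_entries = 0))
  expect_identical(length(sim$corpus), 0L)
  expect_identical(nrow(sim$truth), 0L)
  expect_match(sim$xml, "<mediawiki>")
})

test_that("identical seeds give byte-identical corpora", {
  cfg <- generator_config(n_entries = 200, seed = 42)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$xml, b$xml)
  expect_identical(a$corpus$entries, b$corpus$entries)
  expect_identical(a$truth, b$truth)
  c2 <- generate_corpus(generator_config(n_entries = 200, seed = 43))
  expect_false(identical(a$xml, c2$xml))
})

test_that("planted cause mixture is recovered within binomial bounds", {
  cfg <- generator_config(n_entries = 1000,
                          cause_mixture = c(suicide = 0.3, heart = 0.7),
                          seed = 42)
  sim <- generate_corpus(cfg)
  n_suicide <- sum(sim$truth$cause == "suicide")
  sd3 <- 3 * sqrt(1000 * 0.3 * 0.7)
  expect_lt(abs(n_suicide - 300), sd3)
  expect_identical(n_suicide + sum(sim$truth$cause == "heart"), 1000L)
})

test_that("the generated XML dump is accepted unchanged by parse_dump", {
  sim <- generate_corpus(generator_config(n_entries = 400, seed = 5))
  parsed <- suppressMessages(parse_dump(sim$xml))
  expect_identical(length(parsed), 400L)
  expect_setequal(parsed$entries$actor_name, sim$truth$actor_name)
  expect_identical(sort(parsed$entries$year), sort(sim$truth$year))
  # classification agrees between the XML-parsed and in-memory corpora
  lex <- load_lexicon()
  c_xml <- suppressMessages(classify_corpus(parsed, lex))
  c_mem <- suppressMessages(classify_corpus(sim$corpus, lex))
  expect_identical(c_xml$counts, c_mem$counts)
})

test_that("media mixture flows through generation and the medium filter", {
  cfg <- generator_config(n_entries = 600,
                          media_mixture = c(film = 0.7, television = 0.2,
                                            video_game = 0.1),
                          seed = 9)
  sim <- generate_corpus(cfg)
  parsed <- suppressMessages(parse_dump(sim$xml))
  expect_identical(sort(table(parsed$entries$medium)),
                   sort(table(sim$truth$medium)))
  filtered <- suppressMessages(filter_medium(parsed, "film"))
  expect_identical(length(filtered), sum(sim$truth$medium == "film"))
})

test_that("a perfect pipeline on a template-only corpus scores 1.0", {
  cfg <- generator_config(n_entries = 500, ambiguous_name_fraction = 0,
                          seed = 3)
  sim <- generate_corpus(cfg)
  lex <- load_lexicon(); dict <- load_name_dictionary()
  cr <- suppressMessages(classify_corpus(sim$corpus, lex))
  gr <- suppressMessages(classify_genders(sim$corpus, dict))
  ev <- evaluate_recovery(sim$truth, cr, gr)
  expect_true(all(ev$cause$recall == 1))
  expect_true(all(ev$cause$precision == 1, na.rm = TRUE))
  expect_equal(ev$gender_agreement, 1)
  expect_equal(ev$excluded_fraction, 0)
})

test_that("ambiguous-name fraction drives the excluded fraction", {
  cfg <- generator_config(n_entries = 2000, ambiguous_name_fraction = 0.13,
                          seed = 11)
  sim <- generate_corpus(cfg)
  dict <- load_name_dictionary()
  gr <- suppressMessages(classify_genders(sim$corpus, dict))
  cr <- suppressMessages(classify_corpus(sim$corpus, load_lexicon()))
  ev <- evaluate_recovery(sim$truth, cr, gr)
  sd3 <- 3 * sqrt(0.13 * 0.87 / 2000)
  expect_lt(abs(ev$excluded_fraction - 0.13), sd3)
})

test_that("planted per-cause gender mixture is recovered at scale", {
  # suicide at the published film sample size with P(man) = 0.603
  cfg <- generator_config(n_entries = 2382,
                          cause_mixture = c(suicide = 1),
                          gender_mixture_by_cause = c(suicide = 0.603),
                          ambiguous_name_fraction = 0, seed = 17)
  sim <- generate_corpus(cfg)
  gr <- suppressMessages(classify_genders(sim$corpus, load_name_dictionary()))
  p_man <- mean(gr$assignments$consolidated == "man")
  sd3 <- 3 * sqrt(0.603 * 0.397 / 2382)
  expect_lt(abs(p_man - 0.603), sd3)
})

test_that("evaluate_recovery requires aligned ids", {
  sim <- generate_corpus(generator_config(n_entries = 20, seed = 2))
  cr <- suppressMessages(classify_corpus(sim$corpus, load_lexicon()))
  gr <- suppressMessages(classify_genders(sim$corpus, load_name_dictionary()))
  expect_error(evaluate_recovery(sim$truth[-1, ], cr, gr), "aligned")
})

test_that("write_synthetic_fixture emits the three files", {
  dir <- withr::local_tempdir()
  sim <- generate_corpus(generator_config(n_entries = 30, seed = 4))
  paths <- write_synthetic_fixture(sim, dir, seed = 4)
  expect_true(all(file.exists(paths)))
  back <- read_entries_csv(paths[["entries"]])
  expect_identical(back$entries, sim$corpus$entries)
  expect_match(readLines(paths[["truth"]], n = 1), "seed=4")
})
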