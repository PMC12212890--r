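# End-to-end orchestration: ingest -> medium filter -> cause + gender
# classification -> reference comparison, with a machine-readable manifest.

#' Run the full pipeline and write the report bundle
#'
#' Stages: parse the dump, filter to the allowed media, classify causes and
#' genders, build the film-by-gender table (excluded entries dropped from
#' gender-stratified statistics, retained in overall cause counts), compare
#' against the reference, and write year percentiles, gender tallies, cause
#' counts, the chi-square battery, both figures, and a run manifest.
#' Re-running with identical inputs reproduces identical tables (the
#' manifest timestamp aside).
#'
#' @param config named list (or path to a JSON file with the same fields):
#'   `dump` (XML or CSV path, required), `media` (default `"film"`),
#'   `lexicon`, `names`, `reference` (paths; packaged defaults when `NULL`),
#'   `out_dir` (default `tempfile("cinemort_run")`), `threshold` (default
#'   5), `mode` (`"gof"`/`"independence"`), `figures` (default TRUE).
#' @return a `cm_report` list with `percentiles`, `tally`, `cause_counts`,
#'   `shares`, `battery`, `manifest`, `paths`; invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$dump))
  media <- config$media %||% "film"
  out_dir <- config$out_dir %||% tempfile("cinemort_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  lex_path <- config$lexicon %||% path_extdata("cause_lexicon.json")
  names_path <- config$names %||% path_extdata("names_synthetic.tsv")
  ref_path <- config$reference %||% path_extdata("nvss2021_reference.csv")

  corpus <- stage("ingest", parse_dump(config$dump))
  n_ingested <- nrow(corpus$entries)
  filtered <- stage("filter_medium", filter_medium(corpus, media))
  n_filtered <- nrow(filtered$entries)

  lexicon <- stage("load_lexicon", load_lexicon(lex_path))
  dict <- stage("load_names", load_name_dictionary(names_path))
  ref <- stage("load_reference", load_reference(ref_path))

  pct <- stage("year_percentiles", year_percentiles(filtered))
  causes <- stage("classify_cause", classify_corpus(filtered, lexicon))
  genders <- stage("classify_gender", classify_genders(filtered, dict))

  # overall cause counts (all entries) for the representation scatter
  film_all <- mortality_table(names(causes$counts),
                              men = causes$counts, women = 0L * causes$counts,
                              population_id = filtered$source_id)
  shares <- stage("overall_shares", overall_shares(film_all, ref))
  # gender-stratified film table: excluded entries removed
  kept <- genders$assignments$consolidated != "excluded"
  by_cause <- table(factor(causes$assignments$cause[kept],
                           levels = cause_codes()),
                    factor(genders$assignments$consolidated[kept],
                           levels = c("man", "woman")))
  film_gender <- mortality_table(rownames(by_cause),
                                 men = by_cause[, "man"],
                                 women = by_cause[, "woman"],
                                 population_id = filtered$source_id)
  battery <- stage("run_battery",
                   run_battery(film_gender, ref,
                               threshold = config$threshold %||% 5,
                               mode = config$mode %||% "gof"))

  paths <- c(percentiles = file.path(out_dir, "year_percentiles.csv"),
             tally = file.path(out_dir, "gender_tally.csv"),
             cause_counts = file.path(out_dir, "cause_counts.csv"),
             shares = file.path(out_dir, "shares.csv"),
             battery = file.path(out_dir, "battery.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(pct, paths[["percentiles"]], row.names = FALSE)
  tally_df <- data.frame(
    label = c(names(genders$tally$before), names(genders$tally$after)),
    stage = rep(c("before", "after"),
                c(length(genders$tally$before), length(genders$tally$after))),
    count = c(genders$tally$before, genders$tally$after))
  utils::write.csv(tally_df, paths[["tally"]], row.names = FALSE)
  utils::write.csv(data.frame(cause = names(causes$counts),
                              count = causes$counts, row.names = NULL),
                   paths[["cause_counts"]], row.names = FALSE)
  utils::write.csv(shares, paths[["shares"]], row.names = FALSE)
  utils::write.csv(as.data.frame(battery), paths[["battery"]],
                   row.names = FALSE)

  if (isTRUE(config$figures %||% TRUE)) {
    paths <- c(paths, figure1 = file.path(out_dir, "figure1_shares.png"),
               figure2 = file.path(out_dir, "figure2_gender.png"))
    save_plot(plot_representation(shares), paths[["figure1"]])
    save_plot(plot_gender_ratios(battery), paths[["figure2"]])
  }

  manifest <- list(
    inputs = list(dump = unname(tools::md5sum(config$dump)),
                  lexicon = unname(tools::md5sum(lex_path)),
                  names = unname(tools::md5sum(names_path)),
                  reference = unname(tools::md5sum(ref_path))),
    lexicon_version = lexicon$version,
    name_dictionary = attr(dict, "source"),
    reference_population = attr(ref, "population_id"),
    media = media,
    stage_counts = list(ingested = n_ingested,
                        removed_by_medium = n_ingested - n_filtered,
                        filtered = n_filtered,
                        gender_excluded =
                          unname(genders$tally$after[["excluded"]]),
                        gender_stratified = sum(kept),
                        classified = unname(sum(causes$counts))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  cm_log("run_pipeline", out_dir = out_dir)
  invisible(structure(list(percentiles = pct, tally = genders$tally,
                           cause_counts = causes$counts, shares = shares,
                           battery = battery, manifest = manifest,
                           paths = paths, out_dir = out_dir),
                      class = "cm_report"))
}

save_plot <- function(p, path, width = 7, height = 5) {
  grDevices::png(path, width = width, height = height, units = "in",
                 res = 120)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
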