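# The NVSS 2021 leading-cause-by-gender reference table, shipped as a
# validated plain-text fixture.

#' Load a per-cause, per-gender mortality table
#'
#' Reads a CSV with columns `cause,total,women,men` (the packaged fixture
#' also carries `display_name` and `icd10_range`; `#` lines are provenance
#' comments). Validation requires all 13 cause codes, non-negative integer
#' counts, and flags — without correcting — any row whose `women + men`
#' differs from the printed `total` (the NVSS 2021 diabetes row is such a
#' row).
#'
#' @param fixture path to the reference CSV; default is the packaged NVSS
#'   2021 table.
#' @param population_id identifier stored on the table.
#' @param year reference year.
#' @return a `cm_mortality_table`: data.frame with columns `cause`,
#'   `display_name`, `total`, `women`, `men`, `consistent`, plus
#'   `population_id`/`year` attributes.
#' @export
load_reference <- function(fixture = path_extdata("nvss2021_reference.csv"),
                           population_id = "NVSS-2021", year = 2021L) {
  df <- utils::read.csv(fixture, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("cause", "total", "women", "men")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("reference fixture missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"display_name" %in% names(df)) df$display_name <- df$cause
  absent <- setdiff(cause_codes(), df$cause)
  if (length(absent))
    stop("reference table missing cause row(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  for (cl in c("total", "women", "men")) {
    if (any(is.na(df[[cl]])) || any(df[[cl]] < 0) ||
        any(df[[cl]] != floor(df[[cl]])))
      stop("column '", cl, "' must hold non-negative integer counts",
           call. = FALSE)
  }
  df$consistent <- df$women + df$men == df$total
  if (any(!df$consistent))
    cm_log("load_reference",
           flagged_rows = df$cause[!df$consistent])
  df <- df[match(cause_codes(), df$cause),
           c("cause", "display_name", "total", "women", "men", "consistent")]
  rownames(df) <- NULL
  structure(df, population_id = population_id, year = year,
            class = c("cm_mortality_table", "data.frame"))
}

#' Build a mortality table from counts
#'
#' Constructor used for the film side: per-cause `men`/`women` counts (e.g.
#' from the cause and gender classifiers with excluded entries removed).
#'
#' @param cause,men,women parallel vectors; `cause` values must be valid
#'   codes.
#' @param population_id identifier stored on the table.
#' @param year year label (`NA` for an all-time corpus).
#' @return a `cm_mortality_table`.
#' @export
mortality_table <- function(cause, men, women, population_id = "film",
                            year = NA_integer_) {
  stopifnot(length(cause) == length(men), length(cause) == length(women))
  bad <- setdiff(cause, cause_codes())
  if (length(bad))
    stop("unknown cause code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df <- data.frame(cause = cause_codes(),
                   display_name = cause_codes(),
                   total = 0L, women = 0L, men = 0L, consistent = TRUE,
                   stringsAsFactors = FALSE)
  idx <- match(cause, df$cause)
  df$men[idx] <- as.integer(men)
  df$women[idx] <- as.integer(women)
  df$total <- df$men + df$women
  structure(df, population_id = population_id, year = year,
            class = c("cm_mortality_table", "data.frame"))
}

#' Per-cause gender proportions
#'
#' `p_men = men / (men + women)`; the denominator is the sum of the gender
#' counts, not the printed total, so rows flagged inconsistent still yield
#' well-defined proportions that sum to 1.
#'
#' @param table a `cm_mortality_table`.
#' @param cause a cause code present in the table.
#' @return named numeric vector `c(p_men=, p_women=)`.
#' @export
#' @examples
#' ref <- load_reference()
#' gender_proportion(ref, "suicide")  # p_women ~ 0.204
gender_proportion <- function(table, cause) {
  stopifnot(inherits(table, "cm_mortality_table"), length(cause) == 1L)
  row <- table[table$cause == cause, ]
  if (nrow(row) != 1L)
    stop("cause '", cause, "' not in table", call. = FALSE)
  denom <- row$men + row$women
  if (denom == 0)
    stop("cause '", cause, "' has no gendered deaths; proportion undefined",
         call. = FALSE)
  c(p_men = row$men / denom, p_women = row$women / denom)
}
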