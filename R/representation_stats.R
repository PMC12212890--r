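# Comparison of the classified film corpus with the NVSS reference:
# per-cause representation ratios, per-cause gender proportions, and the
# one-sample goodness-of-fit chi-square battery with the small-count
# applicability rule.

#' Per-cause shares and representation ratios
#'
#' Each cause's share of all deaths is computed within each dataset
#' (film and reference); the representation ratio is
#' `share_film / share_ref`, so ratio > 1 means the cause is overrepresented
#' in film (above the identity line on the share-vs-share plot).
#'
#' @param film_table,ref_table `cm_mortality_table`s over the same cause
#'   vocabulary. Film totals may come from cause classification alone
#'   (gender-excluded entries included).
#' @return data.frame with columns `cause`, `share_film`, `share_ref`,
#'   `representation_ratio` (`NA` with a flag where `share_ref` is 0).
#' @export
overall_shares <- function(film_table, ref_table) {
  stopifnot(inherits(film_table, "cm_mortality_table"),
            inherits(ref_table, "cm_mortality_table"))
  if (sum(film_table$total) == 0)
    stop("film table is empty", call. = FALSE)
  share_film <- film_table$total / sum(film_table$total)
  share_ref <- ref_table$total[match(film_table$cause, ref_table$cause)] /
    sum(ref_table$total)
  ratio <- ifelse(share_ref > 0, share_film / share_ref, NA_real_)
  data.frame(cause = film_table$cause, share_film = share_film,
             share_ref = share_ref, representation_ratio = ratio,
             undefined_ratio = share_ref == 0, stringsAsFactors = FALSE)
}

#' One-sample goodness-of-fit chi-square for a gender split
#'
#' Pearson goodness-of-fit of the observed film gender counts for one cause
#' against the fixed real-life proportion of male deaths for that cause:
#' with `n = film_men + film_women`, expected counts are `n * ref_p_men` and
#' `n * (1 - ref_p_men)`, the statistic is the two-cell
#' `sum((observed - expected)^2 / expected)`, `df = 1`, and the p-value is
#' the upper tail of the chi-square distribution. No continuity correction
#' is applied.
#'
#' @param film_men,film_women observed film death counts by gender.
#' @param ref_p_men reference proportion of male deaths, strictly in (0, 1).
#' @return list with `chi2`, `df` (always 1), `p_value`.
#' @export
#' @examples
#' gender_gof_chisq(477, 171, 384886 / 695547)  # chi2 ~ 87.57
gender_gof_chisq <- function(film_men, film_women, ref_p_men) {
  stopifnot_scalar_count(film_men, "film_men")
  stopifnot_scalar_count(film_women, "film_women")
  n <- film_men + film_women
  if (n == 0)
    stop("no observations: the chi-square test is not applicable",
         call. = FALSE)
  if (!is.numeric(ref_p_men) || length(ref_p_men) != 1L ||
      ref_p_men <= 0 || ref_p_men >= 1)
    stop("`ref_p_men` must lie strictly between 0 and 1", call. = FALSE)
  expected <- c(n * ref_p_men, n * (1 - ref_p_men))
  observed <- c(film_men, film_women)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

# Optional reading of "Pearson chi-square": 2x2 independence test of
# source (film vs reference) x gender. Diverges from the goodness-of-fit
# statistic when the film sample is not negligible relative to the
# reference counts (e.g. suicide), which is why goodness-of-fit is the
# default (it reproduces the published battery).
#' @param ref_men,ref_women reference death counts by gender (independence
#'   mode only).
#' @rdname gender_gof_chisq
#' @export
gender_independence_chisq <- function(film_men, film_women, ref_men,
                                      ref_women) {
  tab <- matrix(c(film_men, film_women, ref_men, ref_women), nrow = 2L)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Small-count applicability rule
#'
#' The chi-square test is reported only for causes with at least `threshold`
#' observed film deaths; below that the battery shows a dash.
#'
#' @param film_count_for_cause observed film death count for the cause.
#' @param threshold minimum observation count (default 5).
#' @return logical.
#' @export
applicability <- function(film_count_for_cause, threshold = 5) {
  stopifnot(film_count_for_cause >= 0)
  film_count_for_cause >= threshold
}

#' Run the per-cause chi-square battery
#'
#' One result row per cause (including `other`), ordered alphabetically by
#' display name. For applicable causes (observed film count at or above the
#' threshold) the goodness-of-fit statistic against the reference gender
#' proportion is computed; inapplicable causes carry `NA` statistics.
#'
#' @param film_table_by_gender a `cm_mortality_table` of film counts with
#'   per-gender counts (gender-excluded entries already removed).
#' @param ref_table the reference `cm_mortality_table`.
#' @param threshold applicability threshold on observed film counts.
#' @param mode `"gof"` (default, one-sample goodness-of-fit) or
#'   `"independence"` (2x2 source-by-gender test).
#' @return a `cm_battery` data.frame: `cause`, `display_name`, `film_men`,
#'   `film_women`, `ref_p_men`, `film_p_men`, `share_film`, `share_ref`,
#'   `representation_ratio`, `chi2`, `df`, `p_value`, `applicable`.
#' @export
run_battery <- function(film_table_by_gender, ref_table, threshold = 5,
                        mode = c("gof", "independence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(film_table_by_gender, "cm_mortality_table"),
            inherits(ref_table, "cm_mortality_table"))
  extra <- setdiff(film_table_by_gender$cause, ref_table$cause)
  if (length(extra))
    stop("film cause(s) absent from reference vocabulary: ",
         paste(extra, collapse = ", "), call. = FALSE)
  shares <- overall_shares(film_table_by_gender, ref_table)
  out <- lapply(seq_len(nrow(film_table_by_gender)), function(i) {
    cause <- film_table_by_gender$cause[i]
    fm <- film_table_by_gender$men[i]
    fw <- film_table_by_gender$women[i]
    n <- fm + fw
    rref <- ref_table[ref_table$cause == cause, ]
    p_ref <- rref$men / (rref$men + rref$women)
    app <- applicability(n, threshold)
    stat <- if (app) {
      if (mode == "gof") gender_gof_chisq(fm, fw, p_ref)
      else gender_independence_chisq(fm, fw, rref$men, rref$women)
    } else list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_)
    sh <- shares[shares$cause == cause, ]
    data.frame(cause = cause, display_name = rref$display_name,
               film_men = fm, film_women = fw,
               ref_p_men = p_ref,
               film_p_men = if (n > 0) fm / n else NA_real_,
               share_film = sh$share_film, share_ref = sh$share_ref,
               representation_ratio = sh$representation_ratio,
               chi2 = stat$chi2, df = stat$df, p_value = stat$p_value,
               applicable = app, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  ord <- c_locale_order(res$display_name)
  res <- res[ord, ]
  rownames(res) <- NULL
  class(res) <- c("cm_battery", "data.frame")
  res
}

# C-locale ordering so e.g. "COVID-19" sorts before "Cancer", matching
# standard uppercase-first table ordering.
c_locale_order <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(x)
}

#' Display-format a p-value
#'
#' Three decimals with `<.001` below 0.001, the usual journal-table format.
#'
#' @param p numeric vector of p-values (`NA` formats as a dash).
#' @return character vector.
#' @export
format_p_value <- function(p) {
  ifelse(is.na(p), "—",
         ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p))))
}

#' @export
print.cm_battery <- function(x, ...) {
  need <- c("display_name", "chi2", "df", "p_value", "applicable")
  if (!all(need %in% names(x)))
    return(invisible(NextMethod()))
  show <- data.frame(`Cause of death` = x$display_name,
                     `Chi-square (df)` = ifelse(x$applicable,
                       sprintf("%.2f (%d)", x$chi2, x$df), "—"),
                     `P value` = format_p_value(x$p_value),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Representation scatter plot (film share vs real-life share)
#'
#' Per-cause within-dataset death shares on log-log axes with the identity
#' line; causes above the line are overrepresented in film. A raw-counts
#' mode plots totals instead of shares.
#'
#' @param shares output of [overall_shares()] (a `display_name` column is
#'   added from the reference when plotted via [run_pipeline()]).
#' @param raw_counts logical; plot raw totals instead of shares.
#' @param film_table,ref_table required when `raw_counts = TRUE`.
#' @return a ggplot object.
#' @export
plot_representation <- function(shares, raw_counts = FALSE,
                                film_table = NULL, ref_table = NULL) {
  if (raw_counts) {
    stopifnot(!is.null(film_table), !is.null(ref_table))
    df <- data.frame(cause = film_table$cause,
                     x = ref_table$total[match(film_table$cause,
                                               ref_table$cause)],
                     y = film_table$total)
    labs <- ggplot2::labs(x = "Real-life deaths (count)",
                          y = "Film deaths (count)")
  } else {
    df <- data.frame(cause = shares$cause, x = shares$share_ref,
                     y = shares$share_film)
    labs <- ggplot2::labs(x = "Share of real-life deaths",
                          y = "Share of film deaths")
  }
  df <- df[df$x > 0 & df$y > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = cause), vjust = -0.6,
                       size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    labs + ggplot2::theme_minimal()
}

#' Per-cause gender-proportion bars, film vs real life
#'
#' @param battery a `cm_battery`.
#' @param drop_empty drop causes with no film deaths (default TRUE, matching
#'   the convention of showing only causes present in the corpus).
#' @return a ggplot object.
#' @export
plot_gender_ratios <- function(battery, drop_empty = TRUE) {
  b <- battery
  if (drop_empty) b <- b[b$film_men + b$film_women > 0, ]
  df <- rbind(
    data.frame(cause = b$display_name, source = "film", gender = "men",
               prop = b$film_p_men),
    data.frame(cause = b$display_name, source = "film", gender = "women",
               prop = 1 - b$film_p_men),
    data.frame(cause = b$display_name, source = "real life", gender = "men",
               prop = b$ref_p_men),
    data.frame(cause = b$display_name, source = "real life",
               gender = "women", prop = 1 - b$ref_p_men))
  ggplot2::ggplot(df, ggplot2::aes(x = source, y = prop,
                                   fill = gender)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~cause) +
    ggplot2::scale_fill_manual(values = c(men = "#4477AA",
                                          women = "#CC6688")) +
    ggplot2::labs(x = NULL, y = "Proportion of deaths") +
    ggplot2::theme_minimal()
}
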