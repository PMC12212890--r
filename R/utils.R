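#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Structured one-line stage logging
#'
#' Emits `cinemort <stage>: key=value ...` via [message()] so tests and the
#' run manifest can assert stage-count conservation from logs.
#' @param stage stage name.
#' @param ... named values to report.
#' @keywords internal
cm_log <- function(stage, ...) {
  kv <- list(...)
  txt <- paste(names(kv), vapply(kv, function(v) paste(v, collapse = ","),
                                 character(1)),
               sep = "=", collapse = " ")
  message("cinemort ", stage, ": ", txt)
}

#' Normalize free text prior to parsing and stemming
#'
#' Decodes a small set of common HTML entities, maps curly quotes and dashes
#' to their ASCII forms, and collapses runs of whitespace. Input is assumed
#' UTF-8.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_text("shot “dead” &amp; buried")
normalize_text <- function(x) {
  x <- enc2utf8(as.character(x))
  ents <- c("&amp;" = "&", "&lt;" = "<", "&gt;" = ">", "&quot;" = "\"",
            "&#39;" = "'", "&apos;" = "'", "&nbsp;" = " ", "&ndash;" = "-",
            "&mdash;" = "-")
  for (e in names(ents)) x <- gsub(e, ents[[e]], x, fixed = TRUE)
  # curly quotes / dashes -> ASCII
  x <- gsub("[‘’‛]", "'", x)
  x <- gsub("[“”‟]", "\"", x)
  x <- gsub("[–—―]", "-", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

path_extdata <- function(file) {
  system.file("extdata", file, package = "cinemort", mustWork = TRUE)
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop("`", name, "` must be a single non-negative integer count",
         call. = FALSE)
}
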