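## Readers/writers for catalogs, time series and fit/rate reports.
## Canonical dialect: TSV, header, UTF-8, Unix newlines. Lengths are
## integer bp at the interface; data go to files, messages to stderr.

#' Read a mutation length catalog from TSV
#'
#' Expects a tab-separated file with a header and at least a `length_bp`
#' column of positive integers; optional columns (`generation`, `type`,
#' `frequency`, and anything else) are preserved. Rows whose `length_bp`
#' does not parse as a positive integer are skipped with a warning, or
#' abort the read under `strict = TRUE`; the number of rejected rows is
#' reported on standard error.
#'
#' @param path Path to a TSV file.
#' @param strict Logical; fail on the first invalid row instead of
#'   skipping (default FALSE).
#' @return A data.frame, one row per mutation event.
#' @export
read_catalog <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("catalog file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"length_bp" %in% names(tab)) {
    stop(sprintf("format error: %s has no `length_bp` column.", path),
         call. = FALSE)
  }
  len <- suppressWarnings(as.numeric(tab$length_bp))
  bad <- !is.finite(len) | len < 1 | len != floor(len)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("format error: %d row(s) of %s have invalid `length_bp` (strict mode).",
                   sum(bad), path), call. = FALSE)
    }
    warning(sprintf("skipped %d row(s) with invalid `length_bp` in %s",
                    sum(bad), path), call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
    len <- len[!bad]
  }
  message(sprintf("read %d mutation record(s) from %s (%d rejected)",
                  nrow(tab), path, sum(bad)))
  tab$length_bp <- as.integer(len)
  rownames(tab) <- NULL
  tab
}

#' Write a mutation catalog to TSV
#'
#' @param catalog A data.frame with at least a `length_bp` column.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  if (!is.data.frame(catalog) || !"length_bp" %in% names(catalog)) {
    stop("`catalog` must be a data.frame with a `length_bp` column.",
         call. = FALSE)
  }
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a mutation time series from TSV
#'
#' Expects a `generation` column plus one or more count channels
#' (e.g. `fixed`, `mean`, `lr`, `spm`); missing channels are tolerated.
#'
#' @param path Path to a TSV file.
#' @return A [mutation_series()].
#' @export
read_series <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"generation" %in% names(tab)) {
    stop(sprintf("format error: %s has no `generation` column.", path),
         call. = FALSE)
  }
  channels <- tab[setdiff(names(tab), "generation")]
  if (ncol(channels) == 0L) {
    stop(sprintf("format error: %s has no count channels.", path),
         call. = FALSE)
  }
  do.call(mutation_series, c(list(generation = tab$generation),
                             as.list(channels)))
}

#' Write a mutation time series to TSV
#'
#' @param series A [mutation_series()] (or plain data.frame).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.report_fields <- function(result) {
  if (inherits(result, "tail_fit")) {
    list(kind = "tail_fit", nu = result$nu, c = result$c,
         alpha = result$alpha,
         window_lo = result$window[1], window_hi = result$window[2],
         pearson_r = result$pearson_r, objective = result$objective,
         n_points = result$n_points)
  } else if (inherits(result, "rate_estimate")) {
    list(kind = "rate_estimate", rate = result$rate, stderr = result$stderr,
         intercept = result$intercept,
         window_max_generation = result$window_max_generation,
         through_origin = result$through_origin, n_points = result$n_points)
  } else {
    stop("`result` must be a tail_fit or rate_estimate.", call. = FALSE)
  }
}

#' Write a fit or rate report
#'
#' Serializes every field of a [fit_powerlaw_tail()] / [fit_levy_scale()]
#' result or an [estimate_rate()] result at full precision. JSON keys are
#' stable; the TSV form has one header row and one value row.
#'
#' @param result A `"tail_fit"` or `"rate_estimate"` object.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  fields <- .report_fields(result)
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    row <- as.data.frame(lapply(fields, function(v) if (is.null(v)) NA else v))
    utils::write.table(row, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return A named list of report fields.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
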