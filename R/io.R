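.required_columns <- c("respondent_id", "country", "block_id", "round",
                       "producer", "efficacy_shown", "endorser",
                       "distributor", "uptake")

#' Read a long-format conjoint dataset
#'
#' Reads comma-separated UTF-8 data with a header row, one row per
#' respondent x round, validates the schema (identifiers, block, integer
#' round >= 1, one column per dimension), optionally checks every level
#' label against a catalog, and preserves any extra columns untouched.
#'
#' @param path CSV path.
#' @param catalog Optional [attribute_catalog][build_catalog] for level
#'   validation.
#' @param quiet Suppress the descriptive log line (default FALSE).
#' @return Validated data.frame.
#' @export
read_conjoint_data <- function(path, catalog = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  miss <- setdiff(.required_columns, names(dat))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  r <- dat$round
  if (anyNA(r) || any(r != as.integer(r)) || any(r < 1)) {
    stop("column 'round' must be integer >= 1")
  }
  dat$round <- as.integer(r)
  if (!is.null(catalog)) {
    for (d in names(catalog)) {
      bad <- !(dat[[d]] %in% catalog[[d]]$levels)
      if (any(bad)) {
        stop("row ", which(bad)[1], ": unknown level '", dat[[d]][bad][1],
             "' in column '", d, "'")
      }
    }
  }
  if (!quiet) {
    message(sprintf(
      "read %s: %d rows | %d respondents | %d countries | rounds %d-%d",
      basename(path), nrow(dat), length(unique(dat$respondent_id)),
      length(unique(dat$country)), min(dat$round), max(dat$round)))
  }
  dat
}

#' Write a long-format conjoint dataset
#'
#' Deterministic comma-separated output: UTF-8, header row, `.` decimal
#' separator, missing values as empty fields, full float precision.
#'
#' @param dataset data.frame to write.
#' @param path Output path.
#' @export
write_conjoint_data <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an estimation result or diagnostic report
#'
#' CSV output carries metadata as `#`-prefixed header comment lines above a
#' deterministic column order; JSON embeds the same metadata and
#' round-trips exactly via [read_results()]. Floats are written at full
#' precision.
#'
#' @param result A `conjoint_fit`, `diagnostic_report`, or plain
#'   data.frame (e.g. [marginal_means()] output).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_results <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(result, "conjoint_fit")) {
    tab <- tidy_fit(result, treatment_only = FALSE)
    meta <- result$meta
    meta$n <- result$n
    meta$n_clusters <- result$n_clusters
  } else if (inherits(result, "diagnostic_report")) {
    tab <- if (!is.null(result$tests) && nrow(result$tests)) result$tests
      else data.frame(term = character(0), estimate = numeric(0),
                      se = numeric(0), statistic = numeric(0),
                      p_value = numeric(0))
    meta <- result[setdiff(names(result), c("tests", "joint"))]
  } else if (is.data.frame(result)) {
    tab <- result
    meta <- list(type = "table")
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (format == "csv") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    flat <- vapply(meta, function(v)
      paste(format(unlist(v), digits = 17, trim = TRUE), collapse = ","),
      character(1))
    writeLines(paste0("# ", names(flat), ": ", flat), con)
    utils::write.csv(format(tab, digits = 17, trim = TRUE,
                            justify = "none"),
                     con, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(meta = meta, results = tab), path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null",
      pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON results file
#'
#' @param path Path written by [write_results()] with `format = "json"`.
#' @return List with `meta` and `results` (data.frame).
#' @export
read_results <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.data.frame(obj$results)) {
    obj$results <- as.data.frame(obj$results, stringsAsFactors = FALSE)
  }
  obj
}
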