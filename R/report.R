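# Report writers: CSV (report rounding applied to sweep tables) and JSON
# (with run metadata embedded).

.report_round <- function(x) {
  if (inherits(x, "wave_sweep")) {
    x <- as.data.frame(x)
    x$matching_percent <- round_half_up(x$matching_percent, 0)
    x$type1_percent <- round_half_up(x$type1_percent, 1)
  }
  as.data.frame(x)
}

#' Write an assessment or sweep report
#'
#' CSV output applies the reporting conventions (sweep matching to whole
#' percent, type-1 to one decimal); JSON output embeds run metadata
#' (package version, seed, configuration) alongside the unrounded records.
#'
#' @param x Data frame (assessment results, sweep table, registry, ...).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default follows the extension.
#' @param seed Seed used by the run, recorded in JSON metadata.
#' @param config Named list of configuration values, recorded in JSON
#'   metadata.
#' @export
write_report <- function(x, path, format = NULL, seed = NULL, config = list()) {
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::write.csv(.report_round(x), path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      metadata = list(package = "wavemetrics",
                      version = as.character(utils::packageVersion("wavemetrics")),
                      seed = seed, config = config),
      records = as.data.frame(x)
    )
    jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report path (CSV or JSON).
#' @return For CSV, the data frame; for JSON, a list with `metadata` and
#'   `records`.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
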