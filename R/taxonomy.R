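# Taxonomic normalisation to the WAVE field resolution and the indicator
# registry.
#
# Volunteers identify organisms in the field without a microscope, so the
# method works at family level with five coarser or finer exceptions:
# Pelecypoda, Hirudinea and Turbellaria are kept at class, Amphipoda at
# order, and the genus Chironomus (blood midges, recognisable by their red
# colour) is kept below family while all other Chironomidae stay at family.

.wave_ranks <- c("class", "subclass", "order", "family", "genus", "species")

.wave_exceptions <- data.frame(
  label = c("Pelecypoda", "Hirudinea", "Turbellaria", "Amphipoda", "Chironomus"),
  rank  = c("class", "class", "class", "order", "genus"),
  stringsAsFactors = FALSE
)

# Spelling variants accepted on input, mapped to the canonical label.
.taxon_aliases <- c(hirudinae = "Hirudinea")

.apply_alias <- function(x) {
  hit <- match(tolower(x), names(.taxon_aliases))
  x[!is.na(hit)] <- .taxon_aliases[hit[!is.na(hit)]]
  x
}

#' Aggregation exceptions of the WAVE taxonomic resolution
#'
#' The WAVE resolution is family level with exactly five exceptions, kept at
#' the rank a field volunteer can reliably distinguish: the classes
#' Pelecypoda, Hirudinea and Turbellaria, the order Amphipoda, and the genus
#' *Chironomus*.
#'
#' @return A data frame with columns `label` and `rank` (five rows).
#' @export
#' @examples
#' wave_exceptions()
wave_exceptions <- function() .wave_exceptions

#' Reduce a taxonomic identification to the WAVE field resolution
#'
#' Maps an identification at any rank to the label used by the presence-only
#' metrics: the family name, except that members of Pelecypoda, Hirudinea or
#' Turbellaria collapse to the class label, members of Amphipoda to
#' `"Amphipoda"`, and the genus *Chironomus* is kept as `"Chironomus"`
#' (other Chironomidae remain `"Chironomidae"`). Matching is
#' case-insensitive and whitespace-trimmed; no fuzzy matching is attempted —
#' an identification whose lineage cannot be resolved is returned flagged
#' `recognized = FALSE` rather than silently dropped or guessed.
#'
#' @param name Taxon name as identified (non-empty string).
#' @param rank Rank of the identification: one of class, subclass, order,
#'   family, genus, species.
#' @param lineage Optional named character vector of ancestor names keyed by
#'   rank (e.g. `c(family = "Gammaridae", order = "Amphipoda")`).
#' @return A list with elements `label` (the WAVE-resolution label), `rank`
#'   (rank of aggregation) and `recognized` (logical; `FALSE` when no family
#'   or exception clade could be resolved).
#' @export
#' @examples
#' reduce_to_wave_resolution("Chironomus", "genus")$label        # "Chironomus"
#' reduce_to_wave_resolution("Stenonema", "genus",
#'   lineage = c(family = "Heptageniidae"))$label                # "Heptageniidae"
#' reduce_to_wave_resolution("Gammaridae", "family",
#'   lineage = c(order = "Amphipoda"))$label                     # "Amphipoda"
reduce_to_wave_resolution <- function(name, rank, lineage = NULL) {
  rank <- match.arg(tolower(trimws(rank)), .wave_ranks)
  name <- .apply_alias(canon_taxon(name))
  if (!nzchar(name)) stop("taxon name must be non-empty")

  lin <- character(0)
  if (length(lineage)) {
    if (is.null(names(lineage)) || any(!nzchar(names(lineage)))) {
      stop("lineage must be a named vector (names are ranks)")
    }
    lin <- .apply_alias(canon_taxon(lineage))
    names(lin) <- tolower(trimws(names(lineage)))
  }
  # identity itself completes the lineage at its own rank
  full <- c(lin, stats::setNames(name, rank))
  full <- full[!duplicated(names(full), fromLast = TRUE)]

  if (!is.na(full["genus"]) && identical(unname(full["genus"]), "Chironomus")) {
    return(list(label = "Chironomus", rank = "genus", recognized = TRUE))
  }
  if ("Amphipoda" %in% full) {
    return(list(label = "Amphipoda", rank = "order", recognized = TRUE))
  }
  cls <- intersect(c("Pelecypoda", "Hirudinea", "Turbellaria"), full)
  if (length(cls)) {
    return(list(label = cls[[1L]], rank = "class", recognized = TRUE))
  }
  if (rank == "family") {
    return(list(label = name, rank = "family", recognized = TRUE))
  }
  if (!is.na(full["family"])) {
    return(list(label = unname(full["family"]), rank = "family", recognized = TRUE))
  }
  if (rank %in% c("class", "subclass", "order")) {
    # coarse identification outside the exception clades: keep it, flagged,
    # so the caller can log it — it can never match a registry taxon
    return(list(label = name, rank = rank, recognized = FALSE))
  }
  list(label = name, rank = rank, recognized = FALSE)
}

.registry_cols <- c("taxon", "rank", "direction",
                    "freq_non", "freq_slight", "freq_impaired")

#' Construct/validate an indicator registry
#'
#' @param df Data frame with columns `taxon`, `rank`, `direction`
#'   (`"unimpaired"` or `"impaired"`) and optionally the class-conditional
#'   occurrence frequencies `freq_non`, `freq_slight`, `freq_impaired`.
#' @return The validated data frame with class `wave_registry`.
#' @export
as_wave_registry <- function(df) {
  if (!is.data.frame(df)) stop("registry source must be a data frame")
  if (nrow(df) == 0L) {
    warning("empty indicator registry")
    out <- data.frame(taxon = character(0), rank = character(0),
                      direction = character(0), freq_non = numeric(0),
                      freq_slight = numeric(0), freq_impaired = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("wave_registry", "data.frame")
    return(out)
  }
  need <- c("taxon", "rank", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("registry is missing columns: ", paste(miss, collapse = ", "))
  df$taxon <- .apply_alias(canon_taxon(df$taxon))
  df$rank <- tolower(trimws(df$rank))
  df$direction <- tolower(trimws(df$direction))
  bad <- which(!nzchar(df$taxon) | !(df$direction %in% c("unimpaired", "impaired")) |
                 !(df$rank %in% .wave_ranks))
  if (length(bad)) {
    stop("malformed registry row(s): ", paste(bad, collapse = ", "))
  }
  for (col in c("freq_non", "freq_slight", "freq_impaired")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))) {
      stop("frequencies in column ", col, " must lie in [0, 1]")
    }
  }
  key <- tolower(df$taxon)
  for (t in unique(key[duplicated(key)])) {
    dirs <- unique(df$direction[key == t])
    if (length(dirs) > 1L) {
      stop("taxon '", df$taxon[match(t, key)],
           "' listed with conflicting directions")
    }
  }
  if (anyDuplicated(key)) {
    warning("dropping ", sum(duplicated(key)), " duplicate registry row(s)")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  out <- df[, .registry_cols]
  rownames(out) <- NULL
  class(out) <- c("wave_registry", "data.frame")
  out
}

#' Load an indicator registry (packaged WAVE registry by default)
#'
#' With no argument this loads the registry distributed with the package:
#' 32 indicators of unimpaired condition and 16 indicators of impaired
#' condition, each with its occurrence frequency in non-impacted, slightly
#' impacted and impaired training samples.
#'
#' @param source Path to a CSV or JSON file in the registry schema
#'   (columns `taxon`, `rank`, `direction`, `freq_non`, `freq_slight`,
#'   `freq_impaired`), or `NULL` for the packaged registry.
#' @param quiet Suppress the entry-count message.
#' @return A `wave_registry` data frame.
#' @seealso [write_registry()], [wave_reference_registry()]
#' @export
load_indicator_registry <- function(source = NULL, quiet = FALSE) {
  if (is.null(source)) {
    source <- system.file("extdata", "wave_indicators.csv",
                          package = "wavemetrics", mustWork = TRUE)
  }
  if (!file.exists(source)) stop("registry file not found: ", source)
  ext <- tolower(tools::file_ext(source))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(source), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(source, stringsAsFactors = FALSE)
  }
  reg <- as_wave_registry(df)
  if (!quiet) {
    message("indicator registry: ", sum(reg$direction == "unimpaired"),
            " unimpaired, ", sum(reg$direction == "impaired"),
            " impaired entries")
  }
  reg
}

#' Write an indicator registry to CSV or JSON
#'
#' @param registry A `wave_registry`.
#' @param path Output path; format follows the file extension unless given.
#' @param format `"csv"` or `"json"`.
#' @export
write_registry <- function(registry, path, format = NULL) {
  stopifnot(inherits(registry, "wave_registry"))
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "json"))
  df <- as.data.frame(registry)
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.wave_registry <- function(x, ...) {
  cat("WAVE indicator registry: ", nrow(x), " taxa (",
      sum(x$direction == "unimpaired"), " unimpaired, ",
      sum(x$direction == "impaired"), " impaired)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
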