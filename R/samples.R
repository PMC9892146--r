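# Sample container and delimited-text I/O.
#
# A sample is a presence set: the distinct WAVE-resolution taxa found in a
# 100-organism kick-sample subsample, optionally labelled with the BAP
# multimetric score (0-10) and/or its four-tier condition category. Counts
# are deliberately never stored — the metrics are presence-only.

.wave_categories <- c("non", "slight", "moderate", "severe")

#' Build a set of presence-only samples
#'
#' @param taxa Named list; each element is a character vector of
#'   WAVE-resolution taxon labels for one sample (deduplicated to a set).
#' @param bap Optional numeric vector of BAP scores in `[0, 10]`, recycled
#'   to `NA` where unknown. When a BAP score is present and `category` is
#'   not, the four-tier category is derived with [assign_category()].
#' @param category Optional character vector: `"non"`, `"slight"`,
#'   `"moderate"` or `"severe"`.
#' @param sample_id Sample identifiers; defaults to `names(taxa)`.
#' @return A data frame of class `wave_samples` with columns `sample_id`,
#'   `bap`, `category` and the list-column `taxa`.
#' @export
#' @examples
#' wave_samples(list(A = c("Perlidae", "Heptageniidae"), B = "Asellidae"),
#'              bap = c(8.2, 3.1))
wave_samples <- function(taxa, bap = NULL, category = NULL,
                         sample_id = names(taxa)) {
  stopifnot(is.list(taxa))
  n <- length(taxa)
  if (is.null(sample_id)) sample_id <- sprintf("S%05d", seq_len(n))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id values")
  if (is.null(bap)) bap <- rep(NA_real_, n)
  bap <- rep_len(as.numeric(bap), n)
  if (any(!is.na(bap) & (bap < 0 | bap > 10))) {
    stop("BAP scores must lie in [0, 10]")
  }
  if (is.null(category)) {
    category <- rep(NA_character_, n)
  } else {
    category <- rep_len(tolower(trimws(as.character(category))), n)
  }
  derive <- is.na(category) & !is.na(bap)
  if (any(derive)) category[derive] <- assign_category(bap[derive])
  if (any(!is.na(category) & !(category %in% .wave_categories))) {
    stop("category must be one of: ", paste(.wave_categories, collapse = ", "))
  }
  taxa <- lapply(taxa, function(t) sort(unique(.apply_alias(canon_taxon(t)))))
  out <- data.frame(sample_id = sample_id, bap = bap, category = category,
                    stringsAsFactors = FALSE)
  out$taxa <- unname(taxa)
  class(out) <- c("wave_samples", "data.frame")
  out
}

#' @export
print.wave_samples <- function(x, ...) {
  cat("wave_samples: ", nrow(x), " samples, ",
      length(unique(unlist(x$taxa))), " distinct taxa\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(x, 5L)
    cat(paste0("  ", show$sample_id,
               " [bap=", ifelse(is.na(show$bap), "NA", format(show$bap)),
               ", ", ifelse(is.na(show$category), "?", show$category), "] ",
               vapply(show$taxa, function(t) paste(utils::head(t, 4L), collapse = ", "),
                      character(1)),
               ifelse(lengths(show$taxa) > 4L, ", ...", "")),
        sep = "\n")
    if (nrow(x) > 5L) cat("  ... and", nrow(x) - 5L, "more samples\n")
  }
  invisible(x)
}

# Effective four-tier category per sample (stored, or derived from BAP).
sample_categories <- function(samples) {
  stopifnot(inherits(samples, "wave_samples"))
  samples$category
}

#' Read presence samples from delimited text
#'
#' Long format: one row per (sample, taxon) with columns `sample_id`,
#' `taxon`, `rank` (a `count` column, if present, is ignored — the metrics
#' are presence-only). Taxa are passed through [reduce_to_wave_resolution()]
#' and deduplicated to sets; unrecognized identifications are kept (they can
#' never match an indicator) and reported with a warning.
#'
#' @param path Path to the sample CSV.
#' @param meta Optional path to a per-sample metadata CSV with columns
#'   `sample_id` and `bap` and/or `category`. Metadata rows whose
#'   `sample_id` has no sample are an error; samples without metadata get
#'   `NA` labels.
#' @param sep Field separator (default comma).
#' @return A `wave_samples` data frame.
#' @export
read_samples <- function(path, meta = NULL, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "taxon", "rank"), names(df))
  if (length(miss)) stop("sample file is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("sample file contains no records")
    out <- wave_samples(stats::setNames(list(), character(0)))
  } else {
    df$sample_id <- as.character(df$sample_id)
    # resolve each distinct (name, rank) pair once
    key <- paste(tolower(trimws(df$taxon)), tolower(trimws(df$rank)), sep = "\r")
    uniq <- !duplicated(key)
    res <- Map(reduce_to_wave_resolution, df$taxon[uniq], df$rank[uniq])
    labels <- vapply(res, `[[`, character(1), "label")
    recog <- vapply(res, `[[`, logical(1), "recognized")
    idx <- match(key, key[uniq])
    labels_row <- labels[idx]
    recog_row <- recog[idx]
    if (any(!recog_row)) {
      bad <- table(labels_row[!recog_row])
      warning("unrecognized taxa kept as-is: ",
              paste0(names(bad), " (", as.integer(bad), ")", collapse = ", "))
    }
    taxa <- split(labels_row, df$sample_id)
    out <- wave_samples(taxa)
  }
  if (!is.null(meta)) {
    md <- utils::read.csv(meta, sep = sep, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(md)) stop("metadata file is missing column: sample_id")
    if (!any(c("bap", "category") %in% names(md))) {
      stop("metadata file needs a 'bap' or 'category' column")
    }
    md$sample_id <- as.character(md$sample_id)
    orphans <- setdiff(md$sample_id, out$sample_id)
    if (length(orphans)) {
      stop("metadata sample_id values with no sample records: ",
           paste(orphans, collapse = ", "))
    }
    i <- match(out$sample_id, md$sample_id)
    bap <- if ("bap" %in% names(md)) as.numeric(md$bap)[i] else rep(NA_real_, nrow(out))
    category <- if ("category" %in% names(md)) as.character(md$category)[i] else NULL
    unlab <- sum(is.na(i))
    out <- wave_samples(stats::setNames(out$taxa, out$sample_id),
                        bap = bap, category = category)
    if (unlab > 0L) message(unlab, " sample(s) have no metadata row")
  }
  out
}

#' Write presence samples to delimited text
#'
#' Inverse of [read_samples()]: a long-format sample file and, when
#' `meta_path` is given, a per-sample metadata file with BAP and category.
#'
#' @param samples A `wave_samples` object.
#' @param path Output path for the long-format taxa file.
#' @param meta_path Optional output path for the metadata file.
#' @export
write_samples <- function(samples, path, meta_path = NULL) {
  stopifnot(inherits(samples, "wave_samples"))
  reg_rank <- function(lbl) {
    i <- match(tolower(lbl), tolower(.wave_exceptions$label))
    ifelse(is.na(i), "family", .wave_exceptions$rank[i])
  }
  long <- data.frame(
    sample_id = rep(samples$sample_id, lengths(samples$taxa)),
    taxon = unlist(samples$taxa, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE
  )
  long$rank <- if (nrow(long)) reg_rank(long$taxon) else character(0)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    md <- data.frame(sample_id = samples$sample_id, bap = samples$bap,
                     category = samples$category, stringsAsFactors = FALSE)
    utils::write.csv(md, meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
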