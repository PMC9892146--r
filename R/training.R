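# Training: condition categories, within-category Sorensen similarity,
# indicator selection, and class-conditional occurrence frequencies.

#' Assign the four-tier condition category from a BAP score
#'
#' BAP bands: non-impacted `[7.5, 10]`, slightly impacted `[5, 7.5)`,
#' moderately impacted `(2.5, 5)`, severely impacted `[0, 2.5]`. Note the
#' impaired/unimpaired *grouping* cut is `BAP <= 5` (see
#' [condition_group()]), so a score of exactly 5 is "slight" in the
#' four-tier system yet grouped impaired.
#'
#' @param bap Numeric vector of BAP scores in `[0, 10]`.
#' @return Character vector: `"non"`, `"slight"`, `"moderate"` or `"severe"`.
#' @export
#' @examples
#' assign_category(c(8, 6, 4, 1))   # non slight moderate severe
assign_category <- function(bap) {
  bap <- as.numeric(bap)
  if (any(is.na(bap)) || any(bap < 0 | bap > 10)) {
    stop("BAP scores must lie in [0, 10]")
  }
  ifelse(bap >= 7.5, "non",
         ifelse(bap >= 5, "slight",
                ifelse(bap > 2.5, "moderate", "severe")))
}

#' Impaired/unimpaired grouping of samples
#'
#' The binary truth grouping used for metric evaluation. When a BAP score is
#' available the cut is `BAP <= 5` (impaired); otherwise the four-tier
#' category is grouped with `{moderate, severe}` impaired and
#' `{non, slight}` unimpaired.
#'
#' @param bap Numeric BAP scores (may be `NA`).
#' @param category Four-tier categories (may be `NA`).
#' @return Character vector `"unimpaired"` / `"impaired"` (`NA` when neither
#'   label is available).
#' @export
condition_group <- function(bap = NULL, category = NULL) {
  n <- max(length(bap), length(category))
  if (is.null(bap)) bap <- rep(NA_real_, n)
  if (is.null(category)) category <- rep(NA_character_, n)
  bap <- rep_len(as.numeric(bap), n)
  category <- rep_len(as.character(category), n)
  out <- rep(NA_character_, n)
  has_bap <- !is.na(bap)
  out[has_bap] <- ifelse(bap[has_bap] <= 5, "impaired", "unimpaired")
  use_cat <- !has_bap & !is.na(category)
  out[use_cat] <- ifelse(category[use_cat] %in% c("moderate", "severe"),
                         "impaired", "unimpaired")
  out
}

#' Sorensen similarity of two presence sets
#'
#' `2|A intersect B| / (|A| + |B|)`, the standard presence/absence community
#' similarity; defined as 0 when both sets are empty.
#'
#' @param a,b Character vectors of taxon labels (treated as sets).
#' @return Similarity in `[0, 1]`.
#' @export
sorensen_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) + length(b) == 0L) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Per-taxon contribution to within-category Sorensen similarity
#'
#' Decomposes total within-category similarity over all sample pairs into
#' per-taxon shares. Each pair `(a, b)` carries weight `2 / (|a| + |b|)` per
#' shared taxon, so the pair's total weight is its Sorensen index; taxon
#' `t`'s contribution is the sum of its weights over pairs containing it in
#' both samples, divided by the total over all taxa. Contributions sum to 1
#' whenever any pair shares a taxon.
#'
#' @param taxa_list List of character vectors, one presence set per sample
#'   (at least two samples).
#' @return Named numeric vector of contributions (all zero, with a warning,
#'   when no pair shares any taxon).
#' @export
#' @examples
#' taxon_contributions(list(c("x", "y"), c("x", "z")))  # x carries all similarity
taxon_contributions <- function(taxa_list) {
  if (!is.list(taxa_list) || length(taxa_list) < 2L) {
    stop("need at least two samples to compute contributions")
  }
  taxa_list <- lapply(taxa_list, unique)
  taxa <- sort(unique(unlist(taxa_list)))
  if (length(taxa) == 0L) {
    warning("no taxa present in any sample; contributions undefined, reported as 0")
    return(stats::setNames(numeric(0), character(0)))
  }
  n <- length(taxa_list)
  M <- matrix(0, n, length(taxa), dimnames = list(NULL, taxa))
  for (i in seq_len(n)) M[i, taxa_list[[i]]] <- 1
  sizes <- rowSums(M)
  W <- 2 / outer(sizes, sizes, "+")   # pair weight per shared taxon
  W[!is.finite(W)] <- 0               # both sets empty
  diag(W) <- 0
  numer <- 0.5 * colSums(M * (W %*% M))
  total <- sum(numer)
  if (total <= 0) {
    warning("all pairwise similarities are zero; contributions reported as 0")
    return(stats::setNames(numeric(length(taxa)), taxa))
  }
  stats::setNames(numer / total, taxa)
}

# Occurrence frequency of every taxon in `universe` over a pool of sets.
occurrence_frequency <- function(taxa_list, universe) {
  if (length(taxa_list) == 0L) return(stats::setNames(numeric(length(universe)), universe))
  counts <- table(factor(unlist(lapply(taxa_list, unique)), levels = universe))
  stats::setNames(as.numeric(counts) / length(taxa_list), universe)
}

#' Select indicator taxa from labelled training samples
#'
#' Reproduces the WAVE selection design: the unimpaired reference pool is
#' the *non-impacted* samples only (BAP > 7.5), the impaired pool is the
#' pooled moderate + severe samples (BAP < 5). A taxon is an
#' unimpaired-indicator when its occurrence frequency in the non-impacted
#' pool exceeds its frequency in the impaired pool *and* it contributes less
#' than `contribution_cutoff` to the Sorensen index of the impaired pool;
#' impaired-indicators are the mirror image. A taxon qualifying for both
#' directions (impossible under strict frequency contrast, guarded anyway)
#' is assigned the direction with the larger frequency ratio, with a
#' message.
#'
#' @param training A `wave_samples` object whose samples carry BAP scores or
#'   categories.
#' @param contribution_cutoff Maximum tolerated share of the opposing
#'   category's Sorensen index (default 0.02, i.e. 2%).
#' @return A `wave_registry` (frequency columns unset; see
#'   [estimate_frequencies()]).
#' @export
select_indicators <- function(training, contribution_cutoff = 0.02) {
  stopifnot(inherits(training, "wave_samples"))
  cat4 <- sample_categories(training)
  if (any(is.na(cat4))) stop("every training sample needs a BAP score or category")
  non_pool <- training$taxa[cat4 == "non"]
  imp_pool <- training$taxa[cat4 %in% c("moderate", "severe")]
  if (length(non_pool) < 2L) stop("non-impacted pool has fewer than 2 samples")
  if (length(imp_pool) < 2L) stop("impaired pool has fewer than 2 samples")

  universe <- sort(unique(unlist(c(non_pool, imp_pool))))
  f_non <- occurrence_frequency(non_pool, universe)
  f_imp <- occurrence_frequency(imp_pool, universe)
  fill <- function(contrib) {
    out <- stats::setNames(numeric(length(universe)), universe)
    out[names(contrib)] <- contrib
    out
  }
  c_imp <- fill(taxon_contributions(imp_pool))
  c_non <- fill(taxon_contributions(non_pool))

  unimp <- f_non > f_imp & c_imp < contribution_cutoff
  imp <- f_imp > f_non & c_non < contribution_cutoff
  both <- unimp & imp
  if (any(both)) {
    ratio_u <- ifelse(f_imp[both] > 0, f_non[both] / f_imp[both], Inf)
    ratio_i <- ifelse(f_non[both] > 0, f_imp[both] / f_non[both], Inf)
    keep_u <- ratio_u >= ratio_i
    message("tie-break applied to taxa selected in both directions: ",
            paste(universe[both], collapse = ", "))
    unimp[both] <- keep_u
    imp[both] <- !keep_u
  }
  sel <- unimp | imp
  reg_rank <- function(lbl) {
    i <- match(tolower(lbl), tolower(.wave_exceptions$label))
    ifelse(is.na(i), "family", .wave_exceptions$rank[i])
  }
  as_wave_registry(data.frame(
    taxon = universe[sel],
    rank = reg_rank(universe[sel]),
    direction = ifelse(unimp[sel], "unimpaired", "impaired"),
    stringsAsFactors = FALSE
  ))
}

#' Estimate class-conditional frequencies and category priors
#'
#' For every registry taxon, the proportion of samples containing it in each
#' of the three classes used by the naive Bayes posterior: non-impacted,
#' slightly impacted, and impaired (moderate and severe pooled). Priors are
#' the class proportions of the training set. Frequencies are exact
#' containment proportions — zeros are kept as zeros; any smoothing is an
#' assessment-time option.
#'
#' @param training A `wave_samples` object, every sample categorized.
#' @param registry A `wave_registry`.
#' @return A list with `registry` (the input registry with `freq_non`,
#'   `freq_slight`, `freq_impaired` filled in) and `priors` (named numeric
#'   `non`/`slight`/`impaired`, summing to 1, with the class counts as
#'   attribute `"counts"`).
#' @export
estimate_frequencies <- function(training, registry) {
  stopifnot(inherits(training, "wave_samples"), inherits(registry, "wave_registry"))
  cat4 <- sample_categories(training)
  if (any(is.na(cat4))) stop("every training sample needs a BAP score or category")
  cls <- ifelse(cat4 == "non", "non", ifelse(cat4 == "slight", "slight", "impaired"))
  counts <- table(factor(cls, levels = c("non", "slight", "impaired")))
  empty <- names(counts)[counts == 0L]
  if (length(empty)) stop("no training samples in category: ", paste(empty, collapse = ", "))
  for (class_name in c("non", "slight", "impaired")) {
    pool <- training$taxa[cls == class_name]
    f <- occurrence_frequency(pool, registry$taxon)
    registry[[paste0("freq_", class_name)]] <- as.numeric(f)
  }
  priors <- as.numeric(counts) / sum(counts)
  names(priors) <- names(counts)
  attr(priors, "counts") <- stats::setNames(as.integer(counts), names(counts))
  list(registry = registry, priors = priors)
}

#' Summarise registry frequencies by direction and category
#'
#' Median and quartiles of each direction's occurrence frequencies in each
#' class column. Quantiles use linear interpolation of order statistics at
#' `h = (n - 1) p + 1` (R's type 7); reported values are rounded half-up to
#' `digits` decimals.
#'
#' @param registry A `wave_registry` with frequency columns populated.
#' @param digits Decimals for reporting (default 2).
#' @return Data frame with columns `direction`, `category`, `n`, `q25`,
#'   `median`, `q75`.
#' @export
summarize_frequencies <- function(registry, digits = 2) {
  stopifnot(inherits(registry, "wave_registry"))
  out <- list()
  for (dir in c("unimpaired", "impaired")) {
    rows <- registry[registry$direction == dir, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("no entries with direction '", dir, "'; omitted from summary")
      next
    }
    for (class_name in c("non", "slight", "impaired")) {
      x <- rows[[paste0("freq_", class_name)]]
      if (all(is.na(x))) next
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        direction = dir, category = class_name, n = sum(!is.na(x)),
        q25 = round_half_up(q[[1L]], digits),
        median = round_half_up(q[[2L]], digits),
        q75 = round_half_up(q[[3L]], digits),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
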