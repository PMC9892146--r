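# Metric evaluation: threshold sweeps of matching-assessment and
# type-1-error percentages, TPI ranking for follow-up, and trend arithmetic.
#
# Denominator convention (asymmetric, deliberate): matching_percent is
# relative to the samples whose true condition is the target ("identified
# x% of the unimpaired samples"), while type1_percent is relative to ALL
# evaluated samples — the reading under which 2 wrong confident calls among
# 1421 samples is 0.1%.

.new_sweep <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("wave_sweep", "data.frame")
  df
}

.sweep_truth <- function(samples) {
  truth <- condition_group(bap = samples$bap, category = samples$category)
  n_na <- sum(is.na(truth))
  if (n_na > 0L) {
    message(n_na, " sample(s) without BAP or category excluded from sweep")
  }
  truth
}

.sweep_one <- function(trigger_value, truth, thresholds, metric, direction) {
  keep <- !is.na(truth)
  trigger_value <- trigger_value[keep]
  truth <- truth[keep]
  n_total <- length(truth)
  n_target <- sum(truth == direction)
  if (n_target == 0L || n_target == n_total) {
    stop("no samples with true condition '",
         if (n_target == 0L) direction else setdiff(c("unimpaired", "impaired"), direction),
         "' in the test set")
  }
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(k) {
    hit <- trigger_value >= k
    data.frame(metric = metric, direction = direction, threshold = k,
               matching_percent = 100 * sum(hit & truth == direction) / n_target,
               type1_percent = 100 * sum(hit & truth != direction) / n_total,
               n_target = n_target, n_total = n_total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Threshold sweep of the PTIT metric
#'
#' For each minimum indicator-taxon count `k`, the percentage of
#' truth-matching confident calls among target-condition samples
#' (`matching_percent`) and the percentage of wrong confident calls among
#' all samples (`type1_percent`), for both target conditions.
#'
#' @param test A `wave_samples` object; samples without a BAP score or
#'   category are excluded with a message.
#' @param registry A `wave_registry`.
#' @param thresholds Integer thresholds (default `3:7`).
#' @return A `wave_sweep` data frame with columns `metric`, `direction`,
#'   `threshold`, `matching_percent`, `type1_percent`, `n_target`,
#'   `n_total`.
#' @export
sweep_ptit <- function(test, registry, thresholds = 3:7) {
  stopifnot(inherits(test, "wave_samples"))
  truth <- .sweep_truth(test)
  counts <- vapply(test$taxa, count_indicators, numeric(2), registry = registry)
  .new_sweep(rbind(
    .sweep_one(counts["unimpaired", ], truth, thresholds, "ptit", "unimpaired"),
    .sweep_one(counts["impaired", ], truth, thresholds, "ptit", "impaired")
  ))
}

#' Threshold sweep of the TPI metric
#'
#' As [sweep_ptit()], with the trigger "posterior component at or above the
#' probability threshold": `P(non)` for the unimpaired table, `P(impaired)`
#' for the impaired table. Undefined posteriors never trigger.
#'
#' @param test A `wave_samples` object.
#' @param frequencies A `wave_registry` with frequency columns populated.
#' @param priors Named class priors.
#' @param thresholds Probability thresholds (default
#'   `c(0.50, 0.70, 0.90, 0.95, 0.98)`).
#' @param smoothing Additive smoothing passed to [tpi_posterior()].
#' @return A `wave_sweep` data frame.
#' @export
sweep_tpi <- function(test, frequencies, priors = wave_training_priors(),
                      thresholds = c(0.50, 0.70, 0.90, 0.95, 0.98),
                      smoothing = 0) {
  stopifnot(inherits(test, "wave_samples"))
  truth <- .sweep_truth(test)
  post <- vapply(test$taxa, function(t) {
    p <- tpi_posterior(t, frequencies, priors, smoothing)
    if (isTRUE(attr(p, "undefined"))) c(-Inf, -Inf) else c(p[["non"]], p[["impaired"]])
  }, numeric(2))
  .new_sweep(rbind(
    .sweep_one(post[1L, ], truth, thresholds, "tpi", "unimpaired"),
    .sweep_one(post[2L, ], truth, thresholds, "tpi", "impaired")
  ))
}

#' @export
print.wave_sweep <- function(x, ...) {
  cat("Threshold sweep (matching % of target-condition samples;",
      "type-1 % of all samples)\n")
  df <- as.data.frame(x)
  df$matching_percent <- round_half_up(df$matching_percent, 0)
  df$type1_percent <- round_half_up(df$type1_percent, 1)
  print.data.frame(df)
  invisible(x)
}

#' Rank assessed samples by probability of impairment
#'
#' The TPI posterior of impairment is continuous, which makes it a natural
#' priority score for follow-up investigation of sites that did not receive
#' a confident call. Sort order: `p_impaired` descending, ties broken by
#' `n_impaired_indicators` descending then `sample_id` ascending; samples
#' with undefined posteriors sort last, flagged.
#'
#' @param results Data frame from [assess_samples()].
#' @return The rows of `results` in priority order, with a
#'   `posterior_undefined` flag column.
#' @export
rank_by_impairment <- function(results) {
  if (nrow(results) == 0L) {
    results$posterior_undefined <- logical(0)
    return(results)
  }
  und <- is.na(results$p_impaired)
  key <- ifelse(und, -Inf, results$p_impaired)
  o <- order(und, -key, -results$n_impaired_indicators, results$sample_id)
  out <- results[o, , drop = FALSE]
  out$posterior_undefined <- und[o]
  rownames(out) <- NULL
  out
}

#' Trend arithmetic on one direction of a sweep table
#'
#' Two summaries of how a sweep trades efficiency for confidence as its
#' threshold rises: the mean decrease in matching percentage per threshold
#' step (rounded half-up to an integer, the reporting convention), and the
#' maximum ratio of consecutive type-1 percentages (a value at or below 0.5
#' means every threshold step at least halves the type-1 error; 0/0 steps
#' are excluded).
#'
#' @param sweep A `wave_sweep` (or data frame) with columns `threshold`,
#'   `matching_percent` and `type1_percent` for a single metric and
#'   direction; at least two rows.
#' @return List: `mean_matching_decrease`, `max_type1_ratio` (`NA` if no
#'   valid ratio).
#' @export
trend_summary <- function(sweep) {
  stopifnot(is.data.frame(sweep))
  if (nrow(sweep) < 2L) stop("trend summary needs at least two sweep rows")
  if (length(unique(paste(sweep$metric, sweep$direction))) > 1L &&
      !is.null(sweep$metric)) {
    stop("trend_summary expects a single metric and direction")
  }
  sweep <- sweep[order(sweep$threshold), , drop = FALSE]
  dec <- -diff(sweep$matching_percent)
  t1 <- sweep$type1_percent
  ratios <- t1[-1L] / t1[-length(t1)]
  ratios <- ratios[!is.nan(ratios)]          # 0/0 excluded
  list(mean_matching_decrease = round_half_up(mean(dec)),
       max_type1_ratio = if (length(ratios)) max(ratios) else NA_real_)
}
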