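# Sample assessment: the PTIT count metric and the TPI naive Bayes
# posterior.
#
# Both metrics are presence-only by construction: only indicator taxa
# actually found in a sample enter the computation. A taxon missing from
# the sample contributes nothing — not a factor of (1 - f) — so a sample
# that lost taxa to collection or sorting error can fail to reach a
# threshold (no conclusion) but cannot be pushed toward a wrong confident
# call.

#' Count distinct indicator taxa present in a sample
#'
#' @param taxa Character vector of WAVE-resolution taxon labels (duplicates
#'   are ignored; matching is case-insensitive).
#' @param registry A `wave_registry`.
#' @return Named integer vector `c(unimpaired = , impaired = )`.
#' @export
count_indicators <- function(taxa, registry) {
  stopifnot(inherits(registry, "wave_registry"))
  taxa <- unique(tolower(.apply_alias(canon_taxon(taxa))))
  present <- registry$direction[tolower(registry$taxon) %in% taxa]
  c(unimpaired = sum(present == "unimpaired"),
    impaired = sum(present == "impaired"))
}

#' PTIT call for one sample
#'
#' Presence of threshold indicator taxa: the sample is called unimpaired
#' when at least `k_unimpaired` distinct unimpaired-indicator taxa are
#' present, impaired when at least `k_impaired` impaired-indicators are
#' present, and "no-conclusion" otherwise. Thresholds are inclusive
#' ("minimum number of indicator taxa"). Should both directions trigger the
#' call is no-conclusion with `conflict = TRUE`. The default `k = 6` is the
#' operating point adopted by the WAVE program.
#'
#' @param taxa Character vector of taxon labels.
#' @param registry A `wave_registry`.
#' @param k_unimpaired,k_impaired Minimum distinct indicator counts (>= 1).
#' @return List: `call` (`"unimpaired"`, `"impaired"`, `"no-conclusion"`),
#'   `n_unimpaired`, `n_impaired`, `conflict`.
#' @export
ptit_assess <- function(taxa, registry, k_unimpaired = 6, k_impaired = 6) {
  if (k_unimpaired < 1 || k_impaired < 1) stop("thresholds must be >= 1")
  n <- count_indicators(taxa, registry)
  hit_u <- n[["unimpaired"]] >= k_unimpaired
  hit_i <- n[["impaired"]] >= k_impaired
  call <- if (hit_u && hit_i) "no-conclusion"
          else if (hit_u) "unimpaired"
          else if (hit_i) "impaired"
          else "no-conclusion"
  list(call = call, n_unimpaired = n[["unimpaired"]],
       n_impaired = n[["impaired"]], conflict = hit_u && hit_i)
}

.check_priors <- function(priors) {
  if (is.null(names(priors)) ||
      !all(c("non", "slight", "impaired") %in% names(priors))) {
    stop("priors must be named 'non', 'slight', 'impaired'")
  }
  priors <- priors[c("non", "slight", "impaired")]
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-9) {
    stop("priors must be non-negative and sum to 1")
  }
  priors
}

#' Three-class naive Bayes posterior from present indicator taxa
#'
#' For the indicator taxa present in the sample (both directions), the
#' posterior over the non-impacted (NI), slightly impacted (SL) and
#' impaired (IM) classes is
#' \deqn{P(c \mid sample) = \frac{P(c) \prod_i P(IT_i \mid c)}
#'   {\sum_{c'} P(c') \prod_i P(IT_i \mid c')}}
#' with `P(IT|c)` the class-conditional occurrence frequencies. The empty
#' product is 1, so a sample with no indicator taxa returns the priors.
#' Zero frequencies are used as-is by default: a present taxon never seen
#' in a class forces that class's posterior to 0. If every class has a
#' zero-frequency term the posterior is undefined (0/0) and returned
#' explicitly as such. `smoothing = a > 0` replaces each frequency `f` by
#' `(f + a) / (1 + 2a)` — an explicitly-flagged deviation from the exact
#' containment proportions that guards the all-zero case.
#'
#' @param taxa Character vector of taxon labels in the sample.
#' @param frequencies A `wave_registry` with frequency columns populated.
#' @param priors Named numeric `non`/`slight`/`impaired` summing to 1.
#' @param smoothing Additive smoothing pseudo-frequency (default 0 = off).
#' @return Object of class `tpi_posterior`: named numeric
#'   `c(non, slight, impaired)` summing to 1, or all-`NA` with attribute
#'   `undefined = TRUE`.
#' @export
#' @examples
#' reg <- wave_reference_registry()
#' tpi_posterior("Perlidae", reg, wave_training_priors())
tpi_posterior <- function(taxa, frequencies, priors, smoothing = 0) {
  stopifnot(inherits(frequencies, "wave_registry"), smoothing >= 0)
  priors <- .check_priors(priors)
  fcols <- c("freq_non", "freq_slight", "freq_impaired")
  present <- frequencies[tolower(frequencies$taxon) %in%
                           unique(tolower(.apply_alias(canon_taxon(taxa)))), ,
                         drop = FALSE]
  if (any(is.na(as.matrix(present[, fcols])))) {
    stop("present indicator taxa have missing frequencies")
  }
  fm <- as.matrix(present[, fcols, drop = FALSE])
  if (smoothing > 0) fm <- (fm + smoothing) / (1 + 2 * smoothing)
  loglik <- colSums(log(fm))               # empty product -> 0
  lp <- log(as.numeric(priors)) + loglik
  if (!any(is.finite(lp))) {
    return(structure(stats::setNames(rep(NA_real_, 3),
                                     c("non", "slight", "impaired")),
                     undefined = TRUE, class = "tpi_posterior"))
  }
  lp <- lp - max(lp[is.finite(lp)])
  p <- exp(lp)
  p[!is.finite(p)] <- 0
  structure(stats::setNames(p / sum(p), c("non", "slight", "impaired")),
            undefined = FALSE, class = "tpi_posterior")
}

#' @export
print.tpi_posterior <- function(x, ...) {
  if (isTRUE(attr(x, "undefined"))) {
    cat("TPI posterior: undefined (all classes have zero likelihood)\n")
  } else {
    cat(sprintf("TPI posterior: P(non)=%.4f  P(slight)=%.4f  P(impaired)=%.4f\n",
                x[["non"]], x[["slight"]], x[["impaired"]]))
  }
  invisible(x)
}

#' TPI call from a posterior and a probability threshold
#'
#' Unimpaired when `P(non) >= threshold`, impaired when
#' `P(impaired) >= threshold` (inclusive, "minimum probability"), otherwise
#' no-conclusion. For thresholds above 0.5 at most one class can trigger;
#' at exactly 0.5 the larger posterior wins and an exact tie is
#' no-conclusion. An undefined posterior yields no-conclusion with
#' `undefined = TRUE`.
#'
#' @param posterior A `tpi_posterior` (or named numeric with `non` and
#'   `impaired` components).
#' @param threshold Minimum posterior probability, in `[0.5, 1]`.
#' @return List: `call`, `undefined`.
#' @export
tpi_assess <- function(posterior, threshold = 0.90) {
  if (threshold < 0.5 || threshold > 1) stop("threshold must lie in [0.5, 1]")
  if (isTRUE(attr(posterior, "undefined")) || any(is.na(posterior))) {
    return(list(call = "no-conclusion", undefined = TRUE))
  }
  p_u <- posterior[["non"]]
  p_i <- posterior[["impaired"]]
  hit_u <- p_u >= threshold
  hit_i <- p_i >= threshold
  call <- if (hit_u && hit_i) {
    if (p_u > p_i) "unimpaired" else if (p_i > p_u) "impaired" else "no-conclusion"
  } else if (hit_u) "unimpaired" else if (hit_i) "impaired" else "no-conclusion"
  list(call = call, undefined = FALSE)
}

#' Assess a set of samples with both metrics
#'
#' @param samples A `wave_samples` object.
#' @param frequencies A `wave_registry` with frequency columns populated
#'   (also supplies the indicator directions for PTIT).
#' @param priors Named class priors (default: the packaged training priors).
#' @param k_unimpaired,k_impaired PTIT thresholds (default 6, the WAVE
#'   operating point).
#' @param tpi_threshold TPI probability threshold (default 0.90).
#' @param smoothing Additive smoothing for the posterior (default 0).
#' @return Data frame with one row per sample: indicator counts, PTIT call,
#'   the three posterior components and the TPI call.
#' @export
assess_samples <- function(samples, frequencies,
                           priors = wave_training_priors(),
                           k_unimpaired = 6, k_impaired = 6,
                           tpi_threshold = 0.90, smoothing = 0) {
  stopifnot(inherits(samples, "wave_samples"))
  if (nrow(samples) == 0L) {
    return(data.frame(sample_id = character(0),
                      n_unimpaired_indicators = integer(0),
                      n_impaired_indicators = integer(0),
                      ptit_call = character(0), p_nonimpacted = numeric(0),
                      p_slight = numeric(0), p_impaired = numeric(0),
                      tpi_call = character(0), tpi_undefined = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    taxa <- samples$taxa[[i]]
    pt <- ptit_assess(taxa, frequencies, k_unimpaired, k_impaired)
    post <- tpi_posterior(taxa, frequencies, priors, smoothing)
    tp <- tpi_assess(post, tpi_threshold)
    data.frame(sample_id = samples$sample_id[i],
               n_unimpaired_indicators = pt$n_unimpaired,
               n_impaired_indicators = pt$n_impaired,
               ptit_call = pt$call,
               p_nonimpacted = post[["non"]],
               p_slight = post[["slight"]],
               p_impaired = post[["impaired"]],
               tpi_call = tp$call,
               tpi_undefined = tp$undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
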