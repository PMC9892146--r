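# Synthetic presence/absence communities and exact analytic oracles.
#
# The generator draws each sample's class from the training composition,
# then each taxon's presence independently as Bernoulli with its
# class-conditional frequency — exactly the naive Bayes independence
# assumption. Real stream communities are correlated, so simulated sweep
# percentages are expected to track the analytic Poisson-binomial values
# below, not the percentages observed on field data.

#' Specification for the synthetic community generator
#'
#' Defaults emulate the training composition behind the packaged registry:
#' category proportions 406 non-impacted : 728 slightly impacted :
#' 287 impaired, and the packaged class-conditional occurrence frequencies.
#'
#' @param n_samples Number of samples to generate.
#' @param proportions Named (`non`, `slight`, `impaired`) nonnegative
#'   weights; normalised to sum to 1 (counts accepted).
#' @param frequencies A `wave_registry` with frequency columns populated.
#' @param n_background Number of non-indicator background taxa (labelled
#'   `Bgfam001`, ...) with class-independent presence probability
#'   `background_freq`; default 0.
#' @param background_freq Shared presence probability of background taxa.
#' @param subsample_size If non-`NULL`, emulate the 100-organism field
#'   subsample: per-taxon abundances with a geometric tail are drawn for
#'   the present taxa, `subsample_size` organisms are kept without
#'   replacement, and presence is recomputed from the survivors (off by
#'   default — the metrics consume presence only).
#' @param seed Integer seed; fixes the full output.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_samples,
                           proportions = c(non = 406, slight = 728, impaired = 287),
                           frequencies = wave_reference_registry(),
                           n_background = 0, background_freq = 0.2,
                           subsample_size = NULL, seed = NULL) {
  stopifnot(n_samples >= 1, inherits(frequencies, "wave_registry"))
  if (is.null(names(proportions)) ||
      !setequal(names(proportions), c("non", "slight", "impaired"))) {
    stop("proportions must be named 'non', 'slight', 'impaired'")
  }
  proportions <- proportions[c("non", "slight", "impaired")]
  if (any(proportions < 0) || sum(proportions) <= 0) {
    stop("proportions must be nonnegative with positive sum")
  }
  fm <- as.matrix(frequencies[, c("freq_non", "freq_slight", "freq_impaired")])
  if (any(is.na(fm)) || any(fm < 0 | fm > 1)) {
    stop("frequencies must be populated and lie in [0, 1]")
  }
  if (n_background > 0 && (background_freq < 0 || background_freq > 1)) {
    stop("background_freq must lie in [0, 1]")
  }
  structure(list(n_samples = as.integer(n_samples),
                 proportions = proportions / sum(proportions),
                 frequencies = frequencies,
                 n_background = as.integer(n_background),
                 background_freq = background_freq,
                 subsample_size = if (is.null(subsample_size)) NULL
                                  else as.integer(subsample_size),
                 seed = seed),
            class = "generator_spec")
}

#' Generate a labelled synthetic dataset
#'
#' Each sample draws a class from the spec proportions, then each taxon's
#' presence independently as Bernoulli with that class's frequency. A
#' pseudo-BAP score is drawn uniformly inside the class's band (non:
#' `[7.5, 10]`; slight: `[5, 7.5]`; impaired: `[0, 5]`) so that the class
#' round-trips through [assign_category()] and [condition_group()]; it
#' carries no claim of realism beyond the band. Identical seeds give
#' identical datasets.
#'
#' @param spec A `generator_spec`.
#' @return A `wave_samples` data frame.
#' @export
#' @examples
#' s <- generate_dataset(generator_spec(50, seed = 1))
#' table(condition_group(bap = s$bap))
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_samples
  classes <- c("non", "slight", "impaired")
  cls <- sample(classes, n, replace = TRUE, prob = spec$proportions)
  lo <- c(non = 7.5, slight = 5, impaired = 0)[cls]
  hi <- c(non = 10, slight = 7.5, impaired = 5)[cls]
  bap <- stats::runif(n, lo, hi)

  labels <- spec$frequencies$taxon
  fm <- as.matrix(spec$frequencies[, c("freq_non", "freq_slight", "freq_impaired")])
  if (spec$n_background > 0) {
    labels <- c(labels, sprintf("Bgfam%03d", seq_len(spec$n_background)))
    fm <- rbind(fm, matrix(spec$background_freq, spec$n_background, 3))
  }
  p <- t(fm)[match(cls, classes), , drop = FALSE]       # n x T
  present <- matrix(stats::runif(n * length(labels)), n) < p
  taxa <- apply(present, 1L, function(row) labels[row], simplify = FALSE)

  if (!is.null(spec$subsample_size)) {
    taxa <- lapply(taxa, function(tt) {
      if (length(tt) == 0L) return(tt)
      # geometric-tailed abundances; mean ~10 organisms per present taxon
      ab <- 1L + stats::rgeom(length(tt), prob = 0.1)
      pool <- rep(tt, ab)
      keep <- if (length(pool) > spec$subsample_size) {
        sample(pool, spec$subsample_size)
      } else pool
      sort(unique(keep))
    })
  }
  wave_samples(taxa, bap = bap, sample_id = sprintf("S%05d", seq_len(n)))
}

#' Upper tail of a Poisson-binomial distribution
#'
#' Exact `P(X >= k)` for the number of successes among independent
#' Bernoulli trials with probabilities `probs`, by dynamic-programming
#' convolution of the success-count distribution. This is the analytic
#' model of a PTIT indicator count under class-conditional independence.
#'
#' @param probs Vector of success probabilities in `[0, 1]`.
#' @param k Threshold count (>= 0); `k = 0` returns 1, `k > length(probs)`
#'   returns 0.
#' @return The tail probability.
#' @export
#' @examples
#' poisson_binomial_tail(c(0.5, 0.5), 1)  # 0.75
poisson_binomial_tail <- function(probs, k) {
  stopifnot(all(probs >= 0 & probs <= 1), k >= 0)
  if (k <= 0) return(1)
  if (k > length(probs)) return(0)
  dp <- 1   # P(count = 0..j) after j trials
  for (p in probs) dp <- c(dp * (1 - p), 0) + c(0, dp * p)
  sum(dp[(k + 1L):length(dp)])
}

#' Analytic PTIT performance under the independence model
#'
#' Closed form of the sweep percentages when samples are generated by
#' [generate_dataset()]: with `T_c = P(PoissonBinomial(f_c) >= k)` the tail
#' of the target direction's indicator frequencies in class `c`, the
#' unimpaired-direction sweep has
#' `matching = 100 (p_NI T_NI + p_SL T_SL) / (p_NI + p_SL)` and
#' `type1 = 100 p_IM T_IM`; the impaired direction is the mirror image.
#'
#' @param frequencies A `wave_registry` with frequency columns populated.
#' @param priors Named class priors (`non`, `slight`, `impaired`).
#' @param k Minimum indicator-taxon count.
#' @param direction `"unimpaired"` or `"impaired"`.
#' @return Named numeric `c(matching_percent, type1_percent)`.
#' @export
expected_ptit_performance <- function(frequencies, priors, k,
                                      direction = c("unimpaired", "impaired")) {
  stopifnot(inherits(frequencies, "wave_registry"))
  direction <- match.arg(direction)
  priors <- .check_priors(priors)
  sub <- frequencies[frequencies$direction == direction, , drop = FALSE]
  tail_in <- c(non = poisson_binomial_tail(sub$freq_non, k),
               slight = poisson_binomial_tail(sub$freq_slight, k),
               impaired = poisson_binomial_tail(sub$freq_impaired, k))
  if (direction == "unimpaired") {
    matching <- 100 * (priors[["non"]] * tail_in[["non"]] +
                         priors[["slight"]] * tail_in[["slight"]]) /
      (priors[["non"]] + priors[["slight"]])
    type1 <- 100 * priors[["impaired"]] * tail_in[["impaired"]]
  } else {
    matching <- 100 * tail_in[["impaired"]]
    type1 <- 100 * (priors[["non"]] * tail_in[["non"]] +
                      priors[["slight"]] * tail_in[["slight"]])
  }
  c(matching_percent = matching, type1_percent = type1)
}
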