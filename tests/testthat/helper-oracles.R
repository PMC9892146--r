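# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (full enumeration, explicit pair loops) so they cannot
# share a bug with the implementations they check.

# P(successes >= k) by enumerating all 2^n outcomes.
enum_poisson_binomial_tail <- function(probs, k) {
  n <- length(probs)
  if (k <= 0) return(1)
  if (k > n) return(0)
  total <- 0
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

# Per-taxon Sorensen contributions by explicit loop over sample pairs.
brute_contributions <- function(sets) {
  sets <- lapply(sets, unique)
  taxa <- sort(unique(unlist(sets)))
  num <- stats::setNames(numeric(length(taxa)), taxa)
  tot <- 0
  n <- length(sets)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- sets[[i]]
      b <- sets[[j]]
      if (length(a) + length(b) == 0L) next
      w <- 2 / (length(a) + length(b))
      shared <- intersect(a, b)
      num[shared] <- num[shared] + w
      tot <- tot + w * length(shared)
    }
  }
  if (tot <= 0) return(num * 0)
  num / tot
}

random_taxa_sets <- function(n, pool = paste0("Fam", letters[1:10]), p = 0.35) {
  lapply(seq_len(n), function(i) pool[stats::runif(length(pool)) < p])
}

# Minimal registry: 3 unimpaired + 2 impaired taxa with known frequencies,
# plus one "neutral" taxon with identical frequency in every class.
toy_registry <- function() {
  as_wave_registry(data.frame(
    taxon = c("Fama", "Famb", "Famc", "Famx", "Famy", "Famneutral"),
    rank = "family",
    direction = c("unimpaired", "unimpaired", "unimpaired",
                  "impaired", "impaired", "impaired"),
    freq_non = c(0.8, 0.6, 0.5, 0.05, 0.10, 0.3),
    freq_slight = c(0.4, 0.3, 0.25, 0.20, 0.15, 0.3),
    freq_impaired = c(0.1, 0.05, 0.08, 0.70, 0.50, 0.3),
    stringsAsFactors = FALSE
  ))
}

toy_priors <- function() c(non = 0.3, slight = 0.5, impaired = 0.2)
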