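test_that("indicator counting is a distinct-set intersection per direction", {
  reg <- wave_reference_registry()
  six <- c("Psephenidae", "Athericidae", "Caenidae", "Ephemerellidae",
           "Heptageniidae", "Isonychiidae")
  expect_equal(count_indicators(six, reg), c(unimpaired = 6, impaired = 0))
  expect_equal(count_indicators(character(0), reg),
               c(unimpaired = 0, impaired = 0))
  # duplicates and case do not inflate the count; non-indicators are ignored
  expect_equal(count_indicators(c("Perlidae", "perlidae", " PERLIDAE",
                                  "Baetidae"), reg),
               c(unimpaired = 1, impaired = 0))
  expect_equal(count_indicators(c("Asellidae", "Amphipoda", "Turbellaria"), reg),
               c(unimpaired = 0, impaired = 3))
})

test_that("PTIT calls use inclusive thresholds and report conflicts", {
  reg <- wave_reference_registry()
  six_u <- c("Psephenidae", "Athericidae", "Caenidae", "Ephemerellidae",
             "Heptageniidae", "Isonychiidae")
  expect_equal(ptit_assess(six_u, reg)$call, "unimpaired")
  expect_equal(ptit_assess(six_u[1:5], reg)$call, "no-conclusion")
  expect_equal(ptit_assess(character(0), reg)$call, "no-conclusion")
  expect_error(ptit_assess(six_u, reg, k_unimpaired = 0), ">= 1")
  both <- c(six_u[1:3], "Asellidae", "Amphipoda", "Turbellaria")
  res <- ptit_assess(both, reg, k_unimpaired = 3, k_impaired = 3)
  expect_equal(res$call, "no-conclusion")
  expect_true(res$conflict)
  expect_equal(res$n_unimpaired, 3)
  expect_equal(res$n_impaired, 3)
})

test_that("the posterior reproduces the hand-computed single-taxon case", {
  # Perlidae frequencies (0.73, 0.42, 0.05) with priors 406:728:287; values
  # frozen from independent arithmetic on the Bayes formula.
  p <- tpi_posterior("Perlidae", wave_reference_registry(), wave_training_priors())
  expect_equal(p[["non"]], 0.4808, tolerance = 1e-4)
  expect_equal(p[["impaired"]], 0.0233, tolerance = 1e-3)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("empty samples return the priors and equal-frequency taxa cancel", {
  reg <- toy_registry()
  pri <- toy_priors()
  expect_equal(unname(unclass(tpi_posterior(character(0), reg, pri)))[1:3],
               unname(pri), tolerance = 1e-12)
  # Famneutral has identical frequency in all classes: likelihood cancels
  expect_equal(unname(unclass(tpi_posterior("Famneutral", reg, pri)))[1:3],
               unname(pri), tolerance = 1e-12)
  base <- tpi_posterior(c("Fama", "Famx"), reg, pri)
  plus <- tpi_posterior(c("Fama", "Famx", "Famneutral"), reg, pri)
  expect_equal(as.numeric(plus), as.numeric(base), tolerance = 1e-12)
})

test_that("posterior properties: sums to 1, order-invariant, ratio form", {
  reg <- wave_reference_registry()
  pri <- wave_training_priors()
  set.seed(303)
  for (i in 1:20) {
    taxa <- sample(reg$taxon, sample(1:8, 1))
    p <- tpi_posterior(taxa, reg, pri)
    if (isTRUE(attr(p, "undefined"))) next
    expect_equal(sum(p), 1, tolerance = 1e-9)
    # multiplication order: permute the frequency-table rows
    shuffled <- as_wave_registry(as.data.frame(reg)[sample(nrow(reg)), ])
    p2 <- tpi_posterior(taxa, shuffled, pri)
    expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-12)
    # ratio form: posterior odds = prior odds x product of frequency ratios
    rows <- reg[tolower(reg$taxon) %in% tolower(taxa), ]
    if (all(rows$freq_non > 0) && p[["non"]] > 0) {
      want <- (pri[["impaired"]] / pri[["non"]]) *
        prod(rows$freq_impaired / rows$freq_non)
      expect_equal(p[["impaired"]] / p[["non"]], unname(want), tolerance = 1e-9)
    }
  }
})

test_that("all-zero likelihoods give an explicit undefined posterior", {
  reg <- as_wave_registry(data.frame(
    taxon = "Famghost", rank = "family", direction = "impaired",
    freq_non = 0, freq_slight = 0, freq_impaired = 0))
  p <- tpi_posterior("Famghost", reg, toy_priors())
  expect_true(attr(p, "undefined"))
  expect_true(all(is.na(p)))
  res <- tpi_assess(p)
  expect_equal(res$call, "no-conclusion")
  expect_true(res$undefined)
  # additive smoothing guards the case, flagged as a deviation by argument
  ps <- tpi_posterior("Famghost", reg, toy_priors(), smoothing = 0.5)
  expect_false(attr(ps, "undefined"))
  expect_equal(unname(unclass(ps))[1:3], unname(toy_priors()), tolerance = 1e-12)
})

test_that("a present taxon with zero frequency in one class zeroes that class", {
  reg <- toy_registry()
  reg$freq_impaired[reg$taxon == "Fama"] <- 0
  p <- tpi_posterior("Fama", reg, toy_priors())
  expect_equal(p[["impaired"]], 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("TPI calls compare inclusively against the probability threshold", {
  mk <- function(non, slight, impaired) {
    structure(c(non = non, slight = slight, impaired = impaired),
              undefined = FALSE, class = "tpi_posterior")
  }
  expect_equal(tpi_assess(mk(0.96, 0.03, 0.01), 0.95)$call, "unimpaired")
  expect_equal(tpi_assess(mk(0.05, 0.04, 0.91), 0.95)$call, "no-conclusion")
  expect_equal(tpi_assess(mk(0.01, 0.01, 0.98), 0.98)$call, "impaired")
  expect_equal(tpi_assess(mk(0.5, 0, 0.5), 0.5)$call, "no-conclusion")
  expect_equal(tpi_assess(mk(0.55, 0, 0.45), 0.5)$call, "unimpaired")
  expect_error(tpi_assess(mk(0.9, 0.05, 0.05), 0.3), "\\[0.5, 1\\]")
})

test_that("assess_samples reports both metrics per sample", {
  samples <- wave_samples(
    list(A = c("Fama", "Famb", "Famc"), B = c("Famx", "Famy"), C = "Baetidae"),
    bap = c(8, 3, NA))
  res <- assess_samples(samples, toy_registry(), toy_priors(),
                        k_unimpaired = 3, k_impaired = 2, tpi_threshold = 0.5)
  expect_equal(res$sample_id, c("A", "B", "C"))
  expect_equal(res$n_unimpaired_indicators, c(3, 0, 0))
  expect_equal(res$n_impaired_indicators, c(0, 2, 0))
  expect_equal(res$ptit_call, c("unimpaired", "impaired", "no-conclusion"))
  expect_equal(res$p_nonimpacted[3], unname(toy_priors()["non"]))
  expect_gt(res$p_impaired[2], 0.5)
  expect_equal(res$tpi_call[2], "impaired")
  expect_equal(rowSums(res[, c("p_nonimpacted", "p_slight", "p_impaired")]),
               rep(1, 3), tolerance = 1e-9, ignore_attr = TRUE)
})
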