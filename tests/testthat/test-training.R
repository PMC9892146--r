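test_that("BAP scores map to the four-tier bands with the documented boundaries", {
  expect_equal(assign_category(c(8, 7.5, 6, 5, 4.9, 2.6, 2.5, 0)),
               c("non", "non", "slight", "slight", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(assign_category(10.5), "\\[0, 10\\]")
  expect_error(assign_category(NA), "\\[0, 10\\]")
})

test_that("the impaired grouping cut is BAP <= 5, overriding the four-tier band", {
  expect_equal(condition_group(bap = c(8, 6, 5, 4.99, 1)),
               c("unimpaired", "unimpaired", "impaired", "impaired", "impaired"))
  # a BAP of exactly 5 is 'slight' in four tiers yet grouped impaired
  expect_equal(assign_category(5), "slight")
  expect_equal(condition_group(bap = 5), "impaired")
  # category fallback when no BAP is available
  expect_equal(condition_group(category = c("non", "slight", "moderate", "severe")),
               c("unimpaired", "unimpaired", "impaired", "impaired"))
  expect_true(is.na(condition_group(bap = NA, category = NA)))
})

test_that("Sorensen index matches its closed form and invariants", {
  expect_equal(sorensen_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(sorensen_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(sorensen_index(c("x", "y", "z"), c("y", "z", "w")), 2 * 2 / 6)
  expect_equal(sorensen_index(character(0), character(0)), 0)
  expect_equal(sorensen_index(c("a", "a", "b"), c("a", "b")), 1)  # set semantics
  set.seed(101)
  for (i in 1:25) {
    a <- random_taxa_sets(1)[[1]]
    b <- random_taxa_sets(1)[[1]]
    s <- sorensen_index(a, b)
    expect_identical(s, sorensen_index(b, a))
    expect_gte(s, 0)
    expect_lte(s, 1)
    if (length(a) && setequal(a, b)) expect_equal(s, 1)
  }
})

test_that("taxon contributions decompose within-category similarity", {
  expect_equal(taxon_contributions(list("x", "x")), c(x = 1))
  expect_equal(taxon_contributions(list(c("x", "y"), c("x", "y"))),
               c(x = 0.5, y = 0.5))
  expect_equal(taxon_contributions(list(c("x", "y"), c("x", "z"))),
               c(x = 1, y = 0, z = 0))
  expect_error(taxon_contributions(list("x")), "at least two")
  expect_warning(z <- taxon_contributions(list("a", "b")), "zero")
  expect_equal(unname(z), c(0, 0))
})

test_that("contributions agree with the brute-force pair enumeration", {
  set.seed(202)
  for (rep in 1:15) {
    sets <- random_taxa_sets(sample(3:7, 1))
    if (length(unlist(sets)) == 0) next
    got <- suppressWarnings(taxon_contributions(sets))
    want <- brute_contributions(sets)
    expect_equal(got[sort(names(got))], want[sort(names(want))], tolerance = 1e-12)
    if (sum(want) > 0) expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("indicator selection applies the frequency and contribution rules", {
  # 10 non-impacted samples: Ufam in 8; Cfam (the dominant, shared taxon) in
  # all; 10 impaired samples: Ifam in 8, Ufam in 1, Cfam in all. Cfam has
  # equal frequency in both pools; Ufam contributes ~nothing to impaired
  # similarity; Ifam is absent from the non pool.
  non <- lapply(1:10, function(i) c("Cfam", if (i <= 8) "Ufam"))
  imp <- lapply(1:10, function(i) c("Cfam", if (i <= 8) "Ifam", if (i == 1) "Ufam"))
  training <- wave_samples(c(non, imp),
                           bap = c(rep(8, 10), rep(3, 10)),
                           sample_id = sprintf("t%02d", 1:20))
  reg <- select_indicators(training)
  expect_equal(reg$direction[reg$taxon == "Ufam"], "unimpaired")
  expect_equal(reg$direction[reg$taxon == "Ifam"], "impaired")
  expect_false("Cfam" %in% reg$taxon)  # equal frequency: not "more abundant"
})

test_that("the contribution cutoff excludes taxa common in the opposing pool", {
  # Xfam is more frequent in the non pool but still carries a large share of
  # impaired-pool similarity, so it must not become an unimpaired indicator.
  non <- lapply(1:10, function(i) c("Xfam", "Ufam"))
  imp <- lapply(1:10, function(i) c(if (i <= 6) "Xfam", "Ifam"))
  training <- wave_samples(c(non, imp), bap = c(rep(9, 10), rep(2, 10)),
                           sample_id = sprintf("t%02d", 1:20))
  reg <- select_indicators(training)
  expect_false("Xfam" %in% reg$taxon[reg$direction == "unimpaired"])
  expect_true("Ufam" %in% reg$taxon[reg$direction == "unimpaired"])
  # loosening the cutoff admits it
  reg2 <- select_indicators(training, contribution_cutoff = 0.9)
  expect_true("Xfam" %in% reg2$taxon[reg2$direction == "unimpaired"])
})

test_that("selection pools are non-impacted vs moderate+severe, and must be >= 2", {
  # slight samples never enter the pools
  sl <- wave_samples(list(c("Afam"), c("Afam")), bap = c(6, 6))
  expect_error(select_indicators(sl), "non-impacted pool")
  one_each <- wave_samples(list("Afam", "Bfam", "Afam", "Bfam"),
                           bap = c(8, 8, 3, NA), category = c(NA, NA, NA, NA),
                           sample_id = letters[1:4])
  expect_error(select_indicators(one_each), "BAP score or category")
})

test_that("frequencies are containment proportions and priors the class shares", {
  training <- wave_samples(
    list(c("Fama", "Famx"), c("Fama"), c("Famb"), c("Famc"),   # 4 non
         c("Fama"), c("Famx"),                                  # 2 slight
         c("Famx", "Famy"), c("Famx")),                         # 2 impaired
    bap = c(9, 8, 8, 7.6, 6, 5.5, 4, 1),
    sample_id = sprintf("s%d", 1:8))
  est <- estimate_frequencies(training, toy_registry())
  reg <- est$registry
  expect_equal(reg$freq_non[reg$taxon == "Fama"], 0.5)    # 2 of 4
  expect_equal(reg$freq_slight[reg$taxon == "Fama"], 0.5)
  expect_equal(reg$freq_impaired[reg$taxon == "Fama"], 0) # exact zero
  expect_equal(reg$freq_impaired[reg$taxon == "Famx"], 1)
  expect_equal(as.numeric(est$priors), c(0.5, 0.25, 0.25))
  expect_equal(sum(est$priors), 1, tolerance = 1e-12)
  expect_equal(attr(est$priors, "counts"),
               c(non = 4L, slight = 2L, impaired = 2L))
  no_slight <- wave_samples(list("Fama", "Famx"), bap = c(9, 2))
  expect_error(estimate_frequencies(no_slight, toy_registry()),
               "no training samples in category: slight")
})

test_that("priors computed from the packaged training composition match 406:728:287", {
  pri <- wave_training_priors()
  expect_equal(as.numeric(round(pri, 4)), c(0.2857, 0.5123, 0.2020))
  expect_equal(sum(pri), 1, tolerance = 1e-9)
})

test_that("frequency summaries use type-7 quantiles and handle degenerate columns", {
  reg <- as_wave_registry(data.frame(
    taxon = paste0("Fam", letters[1:4]), rank = "family",
    direction = "unimpaired",
    freq_non = c(0.3, 0.3, 0.3, 0.3),
    freq_slight = c(0.1, 0.2, 0.3, 0.4),
    freq_impaired = c(0, 0, 0, 0)))
  expect_warning(summarize_frequencies(reg), "impaired")
  s <- suppressWarnings(summarize_frequencies(reg))
  const <- s[s$category == "non", ]
  expect_equal(c(const$q25, const$median, const$q75), c(0.3, 0.3, 0.3))
  lin <- s[s$category == "slight", ]
  expect_equal(c(lin$q25, lin$median, lin$q75), c(0.18, 0.25, 0.33))
})
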