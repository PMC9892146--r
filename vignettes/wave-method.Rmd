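---
title: "Presence-only bioassessment: the model behind wavemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only bioassessment: the model behind wavemetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavemetrics)
```

## The problem

Benthic macroinvertebrates are the standard biological indicator for
wadeable streams, and kick-net sampling is simple enough for volunteer
programs. The weakness of volunteer data is not collection but *loss*:
organisms missed in the net, lost in sorting, or misidentified. Any metric
that treats an absent taxon as evidence — species richness, percent-model
affinity, and most multimetric indices — converts those losses into wrong
assessments.

The WAVE approach inverts the logic: only taxa *present* in a sample carry
information. A sample that lost organisms can fail to reach a threshold and
return "no conclusion", but it cannot be pushed toward a confident wrong
call. wavemetrics implements the two presence-only metrics of this design,
the machinery to train them regionally, and a synthetic data model to
validate them.

## Condition labels

Reference truth comes from a 0–10 multimetric index (the Biological
Assessment Profile, BAP), consumed here purely as a label. Four tiers:
non-impacted `[7.5, 10]`, slightly impacted `[5, 7.5)`, moderately impacted
`(2.5, 5)`, severely impacted `[0, 2.5]`. The binary evaluation grouping
cuts at `BAP <= 5` = impaired. Boundary conventions are deliberate and
asymmetric: `7.5` is non-impacted and `2.5` severe (inclusive upper bands),
but `5.0` exactly — although "slight" in four tiers — is grouped impaired,
following the `BAP > 5` / `BAP <= 5` convention of the evaluation tables
the metrics were designed against. `condition_group()` therefore prefers
the BAP score over the four-tier label when both are available.

## Taxonomic resolution

All identifications are reduced to family, the finest level volunteers can
reliably reach by eye, with exactly five exceptions kept at the rank that
is actually distinguishable in the field: the classes Pelecypoda, Hirudinea
and Turbellaria, the order Amphipoda, and the genus *Chironomus* (red
coloration). Matching is case-insensitive with no fuzzy matching: a
misspelled or unresolvable identification is flagged `recognized = FALSE`
and kept, never silently dropped or guessed, because a silent
misassignment would corrupt the presence sets the whole method rests on.
The packaged dictionary intentionally covers only the indicator taxa and
the five exception clades — the resolution *rules*, not a full checklist —
so unknown families pass through at family rank.

## Selecting indicator taxa

Indicators are chosen from labelled training samples by two filters:

1. **Frequency contrast.** A candidate unimpaired indicator must occur in
   a larger proportion of non-impacted samples than of impaired
   (moderate + severe) samples; impaired indicators mirror this.
   "More abundant" is read as occurrence frequency, not mean count — the
   method never uses counts. Only non-impacted samples (not slight) form
   the unimpaired reference pool, sharpening the contrast.
2. **Opposing-similarity screen.** The candidate must contribute less than
   2% to the Sørensen similarity of the *opposing* pool. The Sørensen index
   of two presence sets is \(2|A \cap B| / (|A| + |B|)\). The per-taxon
   decomposition is this package's construction (the selection procedure
   names it without defining it): over all within-pool sample pairs, each
   shared taxon in pair \((a, b)\) earns weight \(2/(|a|+|b|)\), so pair
   weights sum to the pair's Sørensen index and taxon shares sum to one.
   This pairwise-share reading was chosen over a pooled-composite reading
   because it weights taxa by how often they actually drive pairwise
   similarity, and it admits a brute-force oracle (explicit pair
   enumeration) that the vectorised implementation is tested against.

The pairwise computation is \(O(n^2)\) in pool size with a dense
\(n \times n\) weight matrix; at the pool sizes the method targets
(hundreds to a few thousand samples) this stays in BLAS territory and runs
in seconds.

A taxon qualifying in both directions is logically impossible under the
strict frequency contrast, but the tie-break (larger frequency ratio wins,
with a message) is implemented anyway as a guard.

## The two metrics

**PTIT** (presence of threshold indicator taxa) counts *distinct* registry
taxa of each direction present in a sample and calls a condition when a
count reaches its threshold (inclusive). The program operating point is
\(k = 6\) unimpaired indicators.

**TPI** (threshold probability of impairment) is a three-class naive Bayes
posterior over non-impacted (NI), slightly impacted (SL) and impaired (IM):

\[
P(\mathrm{IM} \mid s) =
\frac{P(\mathrm{IM}) \prod_i P(IT_i \mid \mathrm{IM})}
     {\sum_{c \in \{\mathrm{NI}, \mathrm{SL}, \mathrm{IM}\}}
        P(c) \prod_i P(IT_i \mid c)}
\]

where the product runs over the indicator taxa present in the sample —
*both* directions, the literal reading of "each indicator taxon found in
the sample" — and the class-conditional terms are the training occurrence
frequencies. Absent taxa contribute nothing (no \(1 - f\) factors): this
is the presence-only contract, not an approximation. The empty product is
1, so a sample with no indicators returns the priors. "Probability
unimpaired" is the NI posterior exactly (not \(P(NI) + P(SL)\)).

Numerical choices:

* The posterior is computed in log space and renormalised after
  subtracting the finite maximum, so it is invariant (to ~1e-15) to the
  order taxa are multiplied in and safe for long products.
* Zero frequencies are used as-is by default: a present taxon never seen
  in a class legitimately zeroes that class. If *every* class is zeroed
  the posterior is undefined (0/0) and reported explicitly — never a
  silent `NaN` — and the TPI call is "no conclusion" with a flag.
* `smoothing = a` optionally maps every frequency to
  \((f + a)/(1 + 2a)\), an additive pseudo-observation shrink toward 0.5.
  It is off by default because the default must reproduce the exact
  registry arithmetic; it exists as an explicitly-flagged guard for
  screening workflows that cannot tolerate undefined posteriors.

Thresholds are inclusive (`>=`) everywhere, matching their "minimum
number" / "minimum probability" definitions. TPI thresholds live in
`[0.5, 1]`; at exactly 0.5 both classes can trigger and the larger
posterior wins (an exact tie is no conclusion).

## Evaluation conventions

`sweep_ptit()` / `sweep_tpi()` sweep the thresholds (defaults 3–7 taxa and
50/70/90/95/98%) and report, per direction:

* `matching_percent` — confident correct calls as a share of the samples
  *whose true condition is the target*;
* `type1_percent` — confident wrong calls as a share of *all* evaluated
  samples.

The asymmetry is deliberate: it is the only pair of denominators under
which two wrong calls in a 1421-sample test set yield the benchmark 0.1%,
while efficiency statements read "identified x% of the unimpaired
samples". Samples lacking both BAP and category are excluded with a logged
count. Report rounding (CSV output and print method) is whole percent for
matching and one decimal for type-1; internally values stay unrounded.
Quantile summaries of frequency tables use linear interpolation of order
statistics at \(h = (n-1)p + 1\) (R's type 7), with half-up rounding to
two decimals for reporting.

`trend_summary()` condenses a sweep: the mean per-step decrease in
matching percentage (rounded half-up to an integer) and the maximum ratio
of consecutive type-1 values (a value ≤ 0.5 means every step at least
halves the error; 0/0 steps are excluded, a positive value over a zero is
reported as `Inf` rather than hidden). On the packaged reference sweep
table these give 12 and 14 points per added taxon and maximum ratios below
0.5 for both directions.

`rank_by_impairment()` orders samples by the impairment posterior
(descending), a continuous priority score for follow-up of sites that got
no confident call; ties break by impaired-indicator count then sample id,
and undefined posteriors sort last, flagged.

## The synthetic data model and what it can show

`generate_dataset()` draws each sample's class from the training
composition (default 406 : 728 : 287, the class counts behind the packaged
registry priors), then each taxon's presence independently as
Bernoulli with its class-conditional frequency. A pseudo-BAP is drawn
uniformly inside the class band purely so labels round-trip through
`assign_category()`; it claims no realism. Everything is driven by one
seed; identical seeds give identical datasets.

This is *exactly* the naive Bayes independence assumption, which makes the
model a calibration instrument rather than an emulation of real streams:

* Under it, a PTIT indicator count follows a Poisson-binomial
  distribution, so sweep percentages have closed forms.
  `poisson_binomial_tail()` computes exact tails by dynamic-programming
  convolution (tested against full \(2^n\) enumeration), and
  `expected_ptit_performance()` assembles the analytic matching and type-1
  values. Simulated sweeps at \(n = 5000\) are required to agree with
  these within three Monte-Carlo standard errors.
* Frequencies estimated from generated data (2000 samples per class) must
  fall in exact 99% Clopper–Pearson intervals of the generating values for
  at least 95% of taxon-by-class cells.
* Indicator selection re-run on generated data must agree with the
  selection rules applied directly to the generating parameters, using
  \(f_t^2 / \sum_s f_s^2\) as the large-\(n\) limit of the contribution
  share; taxa inside pre-declared boundary bands (frequency contrast
  within 0.05, contribution within [0.015, 0.025] of the 2% cutoff) are
  excluded from the strict comparison because sampling noise can
  legitimately flip them.

Real communities are correlated — taxa co-occur through shared habitat and
water chemistry — so passing these tests shows the *implementation* is
faithful to the model, not that the model's percentages equal field
percentages. Two illustrations of the gap, both visible in the packaged
numbers: the analytic PTIT-6 unimpaired efficiency under independence
lands near 54% with an analytic type-1 rate of ~0.02%, close to the field
benchmark in efficiency but an order of magnitude more optimistic in
error; and three packaged unimpaired indicators (Psephenidae,
Heptageniidae, Philopotamidae) would *fail* the 2% contribution screen if
selection were re-run on independence-model data, because at their
impaired-pool frequencies (0.21 each) the independence model concentrates
more similarity in them than correlated field data did.

The optional `subsample_size = 100` mode emulates the field protocol's
100-organism subsample: per-taxon abundances with a geometric tail
(mean ≈ 10 organisms per present taxon — a nominal choice, documented, not
fitted) are pooled and thinned without replacement, then converted back to
presence. It is off by default because the metrics consume presence only.

Problem sizes in the validation suite — 5000 samples for the sweep oracle,
2000 per class for parameter recovery, full-enumeration oracles up to 10
taxa — were chosen so that Monte-Carlo error is a small fraction of the
tolerances being checked while the whole suite runs in well under a
minute.

## Known limitations

* The packaged registry and priors encode one region's fauna and one
  training composition; the method is regional by construction. Train a
  local registry with `select_indicators()` + `estimate_frequencies()`
  before applying it elsewhere.
* Family-level resolution is known to understate impairment in stressed
  streams relative to genus/species metrics, and the impaired direction of
  both metrics is inefficient (confident but rare calls); the intended
  workflow is to call unimpaired sites with PTIT-6 and *rank* the rest by
  TPI rather than call them.
* The naive Bayes posterior is well-calibrated only to the extent the
  independence assumption holds; on real data treat it as a ranking
  score, which is how `rank_by_impairment()` uses it.
* A handful of reported summary statistics of the registry frequency
  columns (some medians and IQR endpoints) are reproducible only at
  particular quantile conventions; the package fixes one convention
  (type 7, half-up reporting) and documents it rather than switching
  conventions per statistic.
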