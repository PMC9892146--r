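# Packaged reference data: the WAVE indicator registry with its
# class-conditional frequencies, the training-set class priors, and the
# published threshold-sweep reference table used for trend checks.

#' Packaged WAVE indicator registry
#'
#' The registry distributed with the package: 32 unimpaired-condition and
#' 16 impaired-condition indicator taxa with their occurrence frequencies
#' in non-impacted, slightly impacted and impaired training samples. The
#' method is regional by construction — users monitoring other regions
#' should train their own registry with [select_indicators()] and
#' [estimate_frequencies()].
#'
#' @return A `wave_registry` data frame.
#' @export
wave_reference_registry <- function() {
  load_indicator_registry(quiet = TRUE)
}

#' Training-set class priors of the packaged registry
#'
#' Class composition of the training set behind the packaged registry:
#' 406 non-impacted, 728 slightly impacted and 287 impaired samples
#' (1421 in total), as proportions.
#'
#' @return Named numeric (`non`, `slight`, `impaired`) summing to 1, with
#'   the counts as attribute `"counts"`.
#' @export
wave_training_priors <- function() {
  counts <- c(non = 406L, slight = 728L, impaired = 287L)
  structure(counts / sum(counts), counts = counts)
}

#' Published reference sweep table for the packaged registry
#'
#' The matching-assessment and type-1-error percentages reported for the
#' PTIT and TPI metrics on the WAVE method's 1421-sample evaluation set,
#' at the standard thresholds (3-7 indicator taxa; 50-98% minimum
#' probability). Used as input to the trend arithmetic of
#' [trend_summary()]; the underlying samples are not distributed, so these
#' percentages are reference values, not recomputable outputs.
#'
#' @return A `wave_sweep` data frame.
#' @export
wave_reference_sweeps <- function() {
  path <- system.file("extdata", "wave_sweep_reference.csv",
                      package = "wavemetrics", mustWork = TRUE)
  .new_sweep(utils::read.csv(path, stringsAsFactors = FALSE))
}
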