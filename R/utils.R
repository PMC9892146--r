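# Internal helpers shared across modules.

# Round half away from zero (report convention; base round() is half-even).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  # sqrt(eps) guard keeps values like 0.325 (stored just below .5 ulp) on
  # the half-up side
  sign(x) * floor(abs(x) * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

# Canonical form of a taxon label: trimmed, single-spaced, capitalised first
# letter. Matching elsewhere is case-insensitive; this fixes the display form.
canon_taxon <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  cap <- nchar(x) > 0
  x[cap] <- paste0(toupper(substring(x[cap], 1, 1)), tolower(substring(x[cap], 2)))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
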