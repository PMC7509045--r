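`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers/tests can distinguish failure modes
abort_amu <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "amu_error", "error", "condition")))
}

abort_schema     <- function(msg) abort_amu(msg, "amu_schema_error")
abort_validation <- function(msg) abort_amu(msg, "amu_validation_error")
abort_parse      <- function(msg) abort_amu(msg, "amu_parse_error")
abort_domain     <- function(msg) abort_amu(msg, "amu_domain_error")

# round-half-up to an integer count (0.5 always rounds up), used for the
# high-usage target count; base round() would round half to even
round_half_up <- function(x) as.integer(floor(x + 0.5))

is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 1 & x == floor(x)
}

parse_iso_date <- function(x) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
  d[is.na(d) | format(d, "%Y-%m-%d") != as.character(x)] <- NA
  d
}

norm_substance <- function(x) tolower(trimws(as.character(x)))
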