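# Internal helpers: classed error conditions, deterministic sub-seeding,
# half-away-from-zero rounding.

ct_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "cointf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ct_validation_error <- function(fmt, ...) ct_stop("cointf_validation_error", fmt, ...)
ct_io_error         <- function(fmt, ...) ct_stop("cointf_io_error", fmt, ...)
ct_numeric_error    <- function(fmt, ...) ct_stop("cointf_numeric_error", fmt, ...)

# One user-facing seed, one deterministic 31-bit sub-seed per sub-generator.
# Multiplicative-congruential mixing keeps partial pipelines reproducible:
# regenerating only the clinical arm never disturbs the expression stream.
ct_subseed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in seq_len(stream + 1L)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# round() is half-to-even; printed percentages use half away from zero.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# significant-digit formatting shared by all TSV writers
ct_format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
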