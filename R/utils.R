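`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a numeric vector so that read.csv() recovers the exact doubles
# (17 significant digits survive the decimal round trip).
.formatNumeric <- function(x) {
  out <- character(length(x))
  out[!is.na(x)] <- sprintf("%.17g", x[!is.na(x)])
  out[is.na(x)] <- ""
  out
}

# Derive a child seed from a base seed; stays below 2^31.
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 7919) %% 2147483647)
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min)
    stop("'", name, "' must be a single integer >= ", min)
  as.integer(x)
}
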