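# Internal numeric helpers shared across modules.

# log(exp(a) + exp(b)) without overflow; vectorized over b.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

# Deterministic child seed for a named stream, kept below 2^31 so it is a
# valid R integer seed.  Adding a stream never perturbs the draws of another.
child_seed <- function(master, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
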