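# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream; seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible child seed; kept below 2^31 - 1 (R integers are 32-bit).
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647L)
}

# log2 entropy with the 0 * log 0 := 0 convention; `w` must already be a
# probability vector.
entropyBits <- function(w) {
  w <- w[w > 0]
  -sum(w * log2(w))
}

# Missing-value tokens used in mapping files.
.na_tokens <- c("", "NA", "na", "not applicable", "Unknown")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
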