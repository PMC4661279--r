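# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# scoped RNG: run `code` under `seed` without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a reproducible child seed from a parent seed and an index,
# kept below 2^31 - 1 (R integers are 32-bit)
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1009 + 17) %% 2147483647)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}
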