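# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Case-fold a gene symbol for matching; display form is preserved elsewhere.
fold_symbol <- function(x) toupper(trimws(x))

# Deterministic unique: keep first occurrence under case-folding, sort
# lexicographically (C locale via explicit method).
unique_symbols <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  x <- x[!duplicated(fold_symbol(x))]
  x[order(fold_symbol(x), method = "radix")]
}

stop_affnet <- function(...) stop(..., call. = FALSE)

warn_affnet <- function(...) warning(..., call. = FALSE)

# Integer-safe seed derivation for per-component RNG streams: keeps derived
# seeds strictly below 2^31 whatever base seed is supplied.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + stream * 12347L) %% 2147483629
}

reset_rows <- function(df) {
  rownames(df) <- NULL
  df
}
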