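# Shared internal helpers.

# Round half away from zero, the convention used when a percentage such as
# 100 * 299 / 6212 is reported as 4.8 (base R's round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Canonicalise feature identifiers before exact matching: trim whitespace and
# unify the unicode dash family (minus sign, en/em dash) to ASCII hyphen.
normalize_id <- function(x) {
  x <- stringr::str_trim(x)
  stringr::str_replace_all(x, "[‐‑‒–—−]", "-")
}

# C-locale (radix) sort so node and row ordering is machine-independent.
sort_c <- function(x) sort(x, method = "radix")

# Stop unless all named columns are present.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

# Derive a 32-bit sub-seed from a base seed and a stream label. The constants
# are arbitrary large primes; the point is a deterministic, well-spread map
# from (seed, label) to [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h %% 2147483629 + 1)
}
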