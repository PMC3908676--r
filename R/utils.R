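# Internal helpers shared across modules.

# Locale-independent lexicographic sort (C byte order) so tie-breaks and
# output ordering are identical on every machine.
lex_sort <- function(x) sort(x, method = "radix")

lex_min <- function(x) lex_sort(x)[1L]

# Canonical key for an unordered node pair; "\r" cannot occur in IDs read
# from whitespace-delimited files.
pair_key <- function(u, v) {
  swap <- u > v
  a <- ifelse(swap, v, u)
  b <- ifelse(swap, u, v)
  paste(a, b, sep = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_noncall <- function(...) stop(..., call. = FALSE)
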