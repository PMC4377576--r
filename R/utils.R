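#' Normalize gene symbols
#'
#' Gene/protein identifiers are treated as plain case-insensitive symbols and
#' normalized to upper case with surrounding whitespace stripped. No cross-ID
#' mapping is attempted.
#'
#' @param x character vector of symbols.
#' @return upper-cased, trimmed character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

## Sorted unique fingerprint bit indices (0-based).
as_fingerprint <- function(bits) {
  bits <- sort(unique(as.integer(bits)))
  if (any(is.na(bits))) stop("fingerprint contains non-integer bit indices")
  if (length(bits) && any(bits < 0)) stop("fingerprint bit indices must be non-negative")
  bits
}

## Parse "1,5,17"-style on-bit lists; empty string -> empty fingerprint.
parse_bits <- function(s) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as_fingerprint(strsplit(s, "[,;[:space:]]+")[[1]])
}

format_bits <- function(bits) paste(bits, collapse = ",")

## Round half away from zero (printed-table convention, unlike IEEE round()).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
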