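#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias or synonym mapping is
#' attempted: resolving gene aliases is a data-preparation concern, not a
#' screening concern. Normalization is idempotent.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalizeSymbols(c(" tp53", "KRAS "))
#' @export
normalizeSymbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Percentage of a numerator over a denominator, rounded half-up to 2 decimals
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return `100 * k / n` rounded half-up to two decimal places.
#' @examples
#' overlapPercentage(7088, 16976)
#' @export
overlapPercentage <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), n > 0)
  floor(100 * k / n * 100 + 0.5) / 100
}

# Derive a reproducible 32-bit sub-seed from a global seed and a component
# name, so adding a component to a pipeline never perturbs the streams of the
# others.
subSeed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% (2^31 - 1))
}

# stderr logging, silenced unless options(slnet.verbose = TRUE)
vlog <- function(...) {
  if (isTRUE(getOption("slnet.verbose", FALSE))) {
    message("[slnet] ", sprintf(...))
  }
  invisible(NULL)
}

# round-trippable text rendering of numeric columns for TSV output
.formatNumericCols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}
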