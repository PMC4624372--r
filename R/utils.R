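#' Derive a child seed from a master seed
#'
#' Counter-based scheme (Knuth multiplicative hash modulo a Mersenne prime)
#' so that replicate k of an analysis gets the same seed regardless of
#' execution order, and different counters give effectively independent
#' streams.  All derived seeds fit in a 32-bit integer.
#'
#' @param seed integer master seed.
#' @param index non-negative integer counter.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, index) {
  stopifnot(length(seed) == 1L, length(index) == 1L, index >= 0)
  as.integer((as.numeric(seed) %% 2147483629 + 1 +
              (index + 1) * 2654435761) %% 2147483629) + 1L
}

# Lower median: for an even count, the lower of the two central order
# statistics, so a median OOB error always corresponds to a realisable
# integer confusion out of n samples.
lowerMedian <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

# UniProt-style accession check (classic 6-character form)
isUniprotAccession <- function(x) {
  grepl("^[A-NR-Z][0-9][A-Z0-9]{3}[0-9]$|^[OPQ][0-9][A-Z0-9]{3}[0-9]$", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
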