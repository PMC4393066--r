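# Internal numeric helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Binary Shannon entropy (base 2)
#'
#' Entropy of a two-letter alphabet with success probability `p`, in bits.
#' `0 * log2(0)` is taken as 0, so `h2(0) == h2(1) == 0`.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Numeric vector of entropies in bits, in \[0, 1\].
#' @keywords internal
#' @noRd
h2 <- function(p) {
  out <- numeric(length(p))
  i <- p > 0 & p < 1
  pi <- p[i]
  out[i] <- -pi * log2(pi) - (1 - pi) * log2(1 - pi)
  out
}

# Validate a 0-based half-open interval against a sequence length.
check_interval <- function(start, end, source_length, what = "interval") {
  if (length(start) != 1L || length(end) != 1L ||
      is.na(start) || is.na(end) ||
      start < 0 || end <= start || end > source_length) {
    stop(sprintf("invalid %s [%s, %s) for sequence of length %s",
                 what, format(start), format(end), format(source_length)),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Check that a set of 0-based half-open intervals exactly tiles [0, len).
tiles_exactly <- function(start, end, len) {
  if (length(start) == 0L) return(FALSE)
  o <- order(start)
  start <- start[o]; end <- end[o]
  start[1L] == 0 && end[length(end)] == len &&
    all(end > start) &&
    (length(start) == 1L || all(start[-1L] == end[-length(end)]))
}
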