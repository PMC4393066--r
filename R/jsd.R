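#' Jensen-Shannon divergence between two subsequence compositions
#'
#' The split statistic of the segmentation: for adjacent subsequences with
#' `n_left`/`n_right` bases of which `gc_left`/`gc_right` are G or C,
#'
#' \deqn{D_{JS} = H_2(p) - \frac{n_l}{n} H_2(p_l) - \frac{n_r}{n} H_2(p_r)}
#'
#' where \eqn{H_2} is the binary Shannon entropy in bits and \eqn{p} the
#' pooled GC fraction.  Zero when both parts share one composition, 1 bit
#' when one part is all-GC and the other all-AT in equal amounts.
#'
#' @param n_left,n_right Base counts of the two parts (each > 0); vectorized.
#' @param gc_left,gc_right GC counts of the two parts.
#' @return Divergence in bits, in \[0, 1\].
#' @examples
#' jsd_divergence(4, 4, 4, 0)  # 1 bit
#' jsd_divergence(5, 2, 5, 2)  # 0
#' @export
jsd_divergence <- function(n_left, gc_left, n_right, gc_right) {
  if (any(n_left <= 0) || any(n_right <= 0))
    stop("both parts must be non-empty", call. = FALSE)
  n <- n_left + n_right
  p <- (gc_left + gc_right) / n
  h2(p) - (n_left / n) * h2(gc_left / n_left) -
    (n_right / n) * h2(gc_right / n_right)
}

# Vectorized scan over all admissible split offsets of [a, b) given the
# cumulative GC count vector `cs` (cs[i+1] = GC count of the first i bases).
# Returns list(position = offset within the region, djs) or NULL.
best_split_cum <- function(cs, a, b, min_len) {
  len <- b - a
  if (len < 2 * min_len) return(NULL)
  k <- min_len:(len - min_len)            # left part sizes
  g_total <- cs[b + 1L] - cs[a + 1L]
  g_left <- cs[a + k + 1L] - cs[a + 1L]
  d <- jsd_divergence(k, g_left, len - k, g_total - g_left)
  i <- which.max(d)                       # which.max takes the leftmost tie
  list(position = k[i], djs = d[i])
}

#' Best binary split of a region by maximal Jensen-Shannon divergence
#'
#' Scans every admissible split point (both parts at least `min_len` bp) in
#' one pass over cumulative GC counts and returns the offset maximizing
#' [jsd_divergence()].  Ties are broken toward the smallest offset so the
#' result is deterministic.
#'
#' @inheritParams gc_fraction
#' @param min_len Minimum part length in bp.
#' @return A list with `position` (split offset within the region: the left
#'   part is `[start, start + position)`) and `djs` (bits), or `NULL` when
#'   the region is shorter than `2 * min_len`.
#' @examples
#' s <- gcd_sequence("x", "GGGGAAAA")
#' best_split(s, min_len = 1)  # position 4, djs 1
#' @export
best_split <- function(seq, start = 0, end = seq_length(seq), min_len) {
  check_interval(start, end, seq_length(seq))
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  if (end - start < 2 * min_len) return(NULL)
  ind <- gc_indicator(seq, start, end)
  ind[is.na(ind)] <- 0L                   # N counts as non-GC
  cs <- c(0, cumsum(ind))
  best_split_cum(cs, 0L, end - start, min_len)
}
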