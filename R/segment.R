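#' Recursive Jensen-Shannon segmentation of a sequence region
#'
#' Splits a region at the point of maximal Jensen-Shannon divergence, then
#' recurses into both parts, halting when a segment's maximal divergence no
#' longer exceeds the calibrated null threshold for its own length and GC
#' content ([halting_threshold()]).  The recursion is run with an explicit
#' stack, left part first, so domains are emitted left to right and the
#' result is fully deterministic.
#'
#' The sequence is expected to be N-free (run [strip_ns()] first); any N
#' present is counted as non-GC.
#'
#' @inheritParams gc_fraction
#' @param model A `halting_model` (see [calibrate_halting()],
#'   [default_halting_model()]).
#' @param min_len Minimum domain length in bp (default 3000, the smallest
#'   compositional domain size observed in animal genomes).
#' @return A tibble of domains tiling `[start, end)` with columns `start`,
#'   `end` (0-based half-open), `length`, `gc` (pooled GC fraction) and
#'   `depth` (number of splits above the domain).  A region shorter than
#'   `min_len` is emitted as a single domain with a warning.
#' @examples
#' m <- calibrate_halting(c(6000, 12000), c(0.3, 0.5),
#'                        replicates = 100, min_len = 3000, seed = 1)
#' s <- gcd_sequence("toy", strrep("A", 6000))
#' segment_sequence(s, m, min_len = 3000)
#' @export
segment_sequence <- function(seq, model, min_len = 3000,
                             start = 0, end = seq_length(seq)) {
  stopifnot(inherits(model, "halting_model"))
  check_interval(start, end, seq_length(seq))
  if (end - start < min_len)
    warning(sprintf("region of %d bp shorter than min_len (%d bp); %s",
                    end - start, min_len, "emitting a single domain"),
            call. = FALSE)

  ind <- gc_indicator(seq, start, end)
  ind[is.na(ind)] <- 0L
  cs <- c(0, cumsum(ind))                 # cumulative GC over the region

  res_start <- numeric(0); res_end <- numeric(0); res_depth <- integer(0)
  stack <- list(list(a = 0L, b = end - start, depth = 0L))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sp <- best_split_cum(cs, fr$a, fr$b, min_len)
    accept <- FALSE
    if (!is.null(sp)) {
      p <- (cs[fr$b + 1L] - cs[fr$a + 1L]) / (fr$b - fr$a)
      accept <- sp$djs > halting_threshold(model, fr$b - fr$a, p)
    }
    if (accept) {
      mid <- fr$a + sp$position
      # push right first so the left part is processed next (left-to-right)
      stack[[length(stack) + 1L]] <- list(a = mid, b = fr$b,
                                          depth = fr$depth + 1L)
      stack[[length(stack) + 1L]] <- list(a = fr$a, b = mid,
                                          depth = fr$depth + 1L)
    } else {
      res_start <- c(res_start, fr$a)
      res_end <- c(res_end, fr$b)
      res_depth <- c(res_depth, fr$depth)
    }
  }
  gc <- (cs[res_end + 1L] - cs[res_start + 1L]) / (res_end - res_start)
  abs_start <- start + res_start
  abs_end <- start + res_end
  tibble::tibble(start = abs_start, end = abs_end,
                 length = res_end - res_start, gc = gc, depth = res_depth)
}
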