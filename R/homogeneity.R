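#' Test a domain's compositional homogeneity against its host sequence
#'
#' Compares the variance of the domain's windowed GC series to that of the
#' whole chromosome (or genomic region) the domain resides on, with a
#' one-sided variance-ratio (F) test.  The domain is called homogeneous when
#' its window variance is *not* significantly greater than the
#' chromosome's at level `alpha`; a domain less variable than its host is
#' homogeneous by construction, so only excess variance disqualifies.  The
#' chromosome series includes the domain's own windows.
#'
#' @param domain_gc Windowed GC series of the domain (see [windowed_gc()]).
#' @param chrom_gc Windowed GC series of the host sequence (>= 2 windows).
#' @param alpha One-sided significance level (default 0.05).
#' @return A list of class `homogeneity_verdict`: `is_homogeneous` (flag),
#'   `testable` (FALSE when the domain has fewer than 2 windows, in which
#'   case the verdict defaults to nonhomogeneous), `statistic` (variance
#'   ratio domain/chromosome), `p_value`, `df` (the two degrees of freedom)
#'   and `alpha`.
#' @examples
#' test_homogeneity(c(0.4, 0.4), c(0.2, 0.4, 0.6, 0.4))
#' @export
test_homogeneity <- function(domain_gc, chrom_gc, alpha = 0.05) {
  if (length(chrom_gc) < 2L)
    stop("chromosome series must have at least 2 windows", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (length(domain_gc) < 2L) {
    return(structure(list(is_homogeneous = FALSE, testable = FALSE,
                          statistic = NA_real_, p_value = NA_real_,
                          df = c(NA_real_, length(chrom_gc) - 1),
                          alpha = alpha),
                     class = "homogeneity_verdict"))
  }
  v_d <- var(domain_gc); v_c <- var(chrom_gc)
  if (v_c == 0) {
    # degenerate host: constant windows; equal-variance domain passes
    stat <- if (v_d == 0) 1 else Inf
    p <- if (v_d == 0) 1 else 0
  } else {
    stat <- v_d / v_c
    p <- pf(stat, length(domain_gc) - 1L, length(chrom_gc) - 1L,
            lower.tail = FALSE)
  }
  structure(list(is_homogeneous = p >= alpha, testable = TRUE,
                 statistic = stat, p_value = p,
                 df = c(length(domain_gc) - 1, length(chrom_gc) - 1),
                 alpha = alpha),
            class = "homogeneity_verdict")
}

#' @export
print.homogeneity_verdict <- function(x, ...) {
  cat(sprintf("<homogeneity_verdict> %s (F = %.4g, p = %.4g, df = %g/%g%s)\n",
              if (x$is_homogeneous) "homogeneous" else "nonhomogeneous",
              x$statistic, x$p_value, x$df[1], x$df[2],
              if (x$testable) "" else ", not testable"))
  invisible(x)
}

#' Annotate a segmentation with homogeneity verdicts and window GC spread
#'
#' Computes the host sequence's windowed GC series once, then tests every
#' domain against it with [test_homogeneity()] and records the domain's
#' windowed GC standard deviation.  Rows flagged `is_n_segment` (if the
#' column is present) are skipped and receive `NA` verdicts.
#'
#' @param domains Tibble with 0-based half-open `start`/`end` columns on
#'   `seq` (e.g. from [segment_sequence()]).
#' @param seq The host [gcd_sequence()] the intervals refer to.
#' @param window Window size in bp (default 1024) for both series.
#' @param alpha One-sided significance level (default 0.05).
#' @return `domains` with columns added: `gc_std` (windowed GC standard
#'   deviation, `NA` with fewer than 2 windows), `homogeneity` (1, 0 or
#'   `NA`), `h_statistic` and `h_testable`.
#' @export
annotate_homogeneity <- function(domains, seq, window = 1024, alpha = 0.05) {
  chrom_gc <- windowed_gc(seq, window = window)
  n <- nrow(domains)
  gc_std <- rep(NA_real_, n); hom <- rep(NA_real_, n)
  stat <- rep(NA_real_, n); testable <- rep(NA, n)
  skip <- if ("is_n_segment" %in% names(domains)) domains$is_n_segment
          else rep(FALSE, n)
  for (i in seq_len(n)) {
    if (skip[i]) next
    len <- domains$end[i] - domains$start[i]
    dom_gc <- if (len >= window)
      windowed_gc(seq, domains$start[i], domains$end[i], window = window)
    else numeric(0)
    if (length(dom_gc) >= 2L) gc_std[i] <- sd(dom_gc)
    v <- test_homogeneity_or_default(dom_gc, chrom_gc, alpha)
    hom[i] <- as.numeric(v$is_homogeneous)
    stat[i] <- v$statistic
    testable[i] <- v$testable
  }
  domains$gc_std <- gc_std
  domains$homogeneity <- hom
  domains$h_statistic <- stat
  domains$h_testable <- testable
  domains
}

test_homogeneity_or_default <- function(dom_gc, chrom_gc, alpha) {
  if (length(chrom_gc) < 2L) {
    # single-window host: nothing to compare against; call it homogeneous
    return(list(is_homogeneous = TRUE, testable = FALSE,
                statistic = NA_real_))
  }
  test_homogeneity(dom_gc, chrom_gc, alpha)
}
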