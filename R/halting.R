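#' Calibrate the dynamic halting threshold
#'
#' The segmentation stops splitting a segment when its maximal
#' Jensen-Shannon divergence does not exceed what a compositionally
#' homogeneous segment of the same length and GC content would produce by
#' chance.  This function calibrates that null threshold by Monte Carlo: for
#' each point of a (length, GC) grid it simulates `replicates` i.i.d.
#' homogeneous sequences (each base G/C with probability `gc`), records the
#' maximal admissible divergence of each, and stores the empirical
#' `quantile` of that distribution.  Between grid points the threshold is
#' interpolated bilinearly on (log length, GC); thresholds are made
#' non-increasing in length at each GC by isotonic regression, since longer
#' homogeneous segments have smaller expected maximal divergence.
#'
#' @param lengths Numeric vector (>= 2 values) of segment lengths in bp;
#'   each must be at least `2 * min_len`.
#' @param gcs Numeric vector of GC fractions in (0, 1).
#' @param replicates Simulated homogeneous sequences per grid point
#'   (>= 100).
#' @param quantile Null quantile in (0.5, 1) used as the threshold; with
#'   0.95, about 5% of truly homogeneous segments are split at least once.
#' @param min_len Minimum part length used for admissible splits (must match
#'   the segmentation's `min_len`).
#' @param seed Integer seed; calibration is reproducible given the seed.
#' @return A `halting_model` object.
#' @seealso [halting_threshold()], [write_halting_model()],
#'   [default_halting_model()]
#' @export
calibrate_halting <- function(lengths, gcs, replicates = 1000,
                              quantile = 0.95, min_len = 3000, seed = 42) {
  lengths <- sort(unique(as.numeric(lengths)))
  gcs <- sort(unique(as.numeric(gcs)))
  if (length(lengths) < 2L)
    stop("length grid too sparse: need at least 2 lengths", call. = FALSE)
  if (replicates < 100) stop("replicates must be >= 100", call. = FALSE)
  if (quantile <= 0.5 || quantile >= 1)
    stop("quantile must be in (0.5, 1)", call. = FALSE)
  if (any(lengths < 2 * min_len))
    stop("every grid length must be >= 2 * min_len", call. = FALSE)
  if (any(gcs <= 0 | gcs >= 1))
    stop("gc grid values must be in (0, 1)", call. = FALSE)

  set.seed(seed)
  grid <- expand.grid(length = lengths, gc = gcs)
  thr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    L <- grid$length[i]; p <- grid$gc[i]
    maxima <- vapply(seq_len(replicates), function(r) {
      cs <- c(0, cumsum(runif(L) < p))
      best_split_cum(cs, 0L, L, min_len)$djs
    }, numeric(1))
    thr[i] <- stats::quantile(maxima, probs = quantile, names = FALSE)
  }
  tab <- tibble::tibble(length = grid$length, gc = grid$gc, threshold = thr)
  # Enforce monotone non-increase in length at each GC level.
  tab <- dplyr::bind_rows(lapply(split(tab, tab$gc), function(d) {
    d <- d[order(d$length), , drop = FALSE]
    d$threshold <- -isoreg(log(d$length), -d$threshold)$yf
    d
  }))
  structure(list(table = tab, quantile = quantile, replicates = replicates,
                 min_len = min_len, seed = seed,
                 lengths = lengths, gcs = gcs),
            class = "halting_model")
}

#' @export
print.halting_model <- function(x, ...) {
  cat(sprintf(paste0("<halting_model> quantile %.3f, %d replicates, ",
                     "min_len %d bp, seed %d\n  lengths: %s bp\n  gc: %s\n"),
              x$quantile, x$replicates, x$min_len, x$seed,
              paste(format(x$lengths, trim = TRUE), collapse = ", "),
              paste(format(x$gcs), collapse = ", ")))
  invisible(x)
}

#' Threshold lookup for a segment
#'
#' Evaluates the calibrated null threshold `t(L, p)` for a segment of length
#' `length` bp and pooled GC fraction `gc`, by bilinear interpolation of
#' the log threshold on (log length, GC).  GC values outside the
#' calibration grid are clamped to its range; lengths beyond the grid are
#' extrapolated as a power law on the last log-log slope, lengths below it
#' are clamped.
#'
#' @param model A `halting_model`.
#' @param length Segment length(s) in bp.
#' @param gc Pooled GC fraction(s); recycled against `length`.
#' @return Numeric vector of thresholds (bits), always > 0.
#' @export
halting_threshold <- function(model, length, gc) {
  stopifnot(inherits(model, "halting_model"))
  n <- max(base::length(length), base::length(gc))
  length <- rep_len(as.numeric(length), n)
  gc <- rep_len(as.numeric(gc), n)
  gc <- pmin(max(model$gcs), pmax(min(model$gcs), gc))
  vapply(seq_len(n), function(i) {
    at_p <- vapply(model$gcs, function(g) {
      d <- model$table[model$table$gc == g, , drop = FALSE]
      interp_loglen(d$length, d$threshold, length[i])
    }, numeric(1))
    if (base::length(model$gcs) == 1L) return(at_p)
    approx(model$gcs, at_p, xout = gc[i], rule = 2)$y
  }, numeric(1))
}

# 1-D interpolation of log(threshold) on log(length): thresholds decay
# roughly as a power of length, so this scale interpolates well, stays
# positive, and extrapolates beyond the grid as a power law.  Below the
# grid the smallest-length threshold is used (segments under 2*min_len are
# never tested anyway).
interp_loglen <- function(lens, thr, x) {
  if (x <= lens[1L]) return(thr[1L])
  ll <- log(lens); lt <- log(thr)
  k <- base::length(lens)
  if (x >= lens[k]) {
    slope <- (lt[k] - lt[k - 1L]) / (ll[k] - ll[k - 1L])
    return(exp(lt[k] + slope * (log(x) - ll[k])))
  }
  exp(approx(ll, lt, xout = log(x))$y)
}

#' Serialize a halting model to a plain-text file
#'
#' Metadata is written as `# key: value` header lines followed by a
#' tab-separated `length`/`gc`/`threshold` table, so a calibration can be
#' run once and shipped with an analysis.
#'
#' @param model A `halting_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_halting_model <- function(model, path) {
  stopifnot(inherits(model, "halting_model"))
  hdr <- c(
    sprintf("# quantile: %.17g", model$quantile),
    sprintf("# replicates: %d", model$replicates),
    sprintf("# min_len: %d", model$min_len),
    sprintf("# seed: %d", model$seed)
  )
  writeLines(hdr, path)
  tab <- model$table
  lines <- c("length\tgc\tthreshold",
             sprintf("%.17g\t%.17g\t%.17g",
                     tab$length, tab$gc, tab$threshold))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Read a halting model from a plain-text file
#'
#' @param path Path written by [write_halting_model()].
#' @return A `halting_model`.
#' @export
read_halting_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1L]]
    meta[[kv[1L]]] <- as.numeric(kv[2L])
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", colClasses = "numeric")
  tab <- tibble::as_tibble(tab)
  structure(list(table = tab, quantile = meta$quantile,
                 replicates = as.integer(meta$replicates),
                 min_len = as.integer(meta$min_len),
                 seed = as.integer(meta$seed),
                 lengths = sort(unique(tab$length)),
                 gcs = sort(unique(tab$gc))),
            class = "halting_model")
}

#' Default halting model shipped with the package
#'
#' Calibrated once at quantile 0.95 with 1000 replicates per grid point over
#' lengths 6 kb to 800 kb and GC 0.20 to 0.70 (`min_len` 3000 bp, seed 42);
#' regenerable with [calibrate_halting()] or the `calibrate` CLI subcommand.
#'
#' @return A `halting_model`.
#' @export
default_halting_model <- function() {
  path <- system.file("extdata", "halting_model.tsv", package = "gcdomains")
  if (!nzchar(path)) stop("shipped halting model not found", call. = FALSE)
  read_halting_model(path)
}

#' @rdname tidy.halting_model
#' @export
tidy.halting_model <- function(x, ...) x$table

#' Tidy and summarize a halting model
#'
#' `tidy()` returns the calibrated threshold table (one row per grid point);
#' `glance()` returns a one-row tibble of calibration metadata.
#'
#' @param x A `halting_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.halting_model <- function(x, ...) {
  tibble::tibble(quantile = x$quantile, replicates = x$replicates,
                 min_len = x$min_len, seed = x$seed,
                 n_lengths = length(x$lengths), n_gc = length(x$gcs),
                 min_length = min(x$lengths), max_length = max(x$lengths))
}

#' Plot a halting model's threshold surface
#'
#' @param object A `halting_model`.
#' @param ... Unused.
#' @return A ggplot: threshold (bits) against segment length (log scale),
#'   one line per GC level.
#' @export
autoplot.halting_model <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$length, y = .data$threshold,
                               colour = factor(.data$gc))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10(labels = scales_bp) +
    ggplot2::labs(x = "segment length (bp)",
                  y = expression(D[JS] ~ "threshold (bits)"),
                  colour = "GC") +
    ggplot2::theme_minimal()
}
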