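#' Specify a synthetic mosaic genome
#'
#' Describes a block-structured test genome: an ordered set of compositional
#' blocks (length and GC fraction each), optional N islands spliced in at
#' stated positions, and a seed making generation reproducible.  The spec is
#' the ground truth that segmentation benchmarks are scored against.
#'
#' @param blocks Data frame (or tibble) with columns `length` (bp, positive)
#'   and `gc` (fraction in \[0, 1\]), one row per block in genome order.
#' @param n_islands Optional data frame with columns `at` (0-based insertion
#'   offset in the island-free assembled sequence, strictly increasing and
#'   distinct — overlapping islands are an error) and `length` (bp).
#' @param seed Integer seed.
#' @param id Sequence id for the generated record.
#' @return An object of class `synthetic_genome_spec`.
#' @examples
#' synthetic_genome_spec(tibble::tibble(length = c(5e4, 5e4),
#'                                      gc = c(0.3, 0.6)))
#' @export
synthetic_genome_spec <- function(blocks, n_islands = NULL, seed = 1,
                                  id = "synthetic") {
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("length", "gc") %in% names(blocks)), nrow(blocks) >= 1)
  if (any(blocks$length < 1)) stop("block lengths must be positive",
                                   call. = FALSE)
  if (any(blocks$gc < 0 | blocks$gc > 1))
    stop("block gc must be in [0, 1]", call. = FALSE)
  base_len <- sum(blocks$length)
  if (!is.null(n_islands)) {
    n_islands <- tibble::as_tibble(n_islands)
    stopifnot(all(c("at", "length") %in% names(n_islands)))
    if (any(n_islands$length < 1))
      stop("island lengths must be positive", call. = FALSE)
    if (anyDuplicated(n_islands$at) || is.unsorted(n_islands$at,
                                                   strictly = TRUE))
      stop("overlapping or unsorted islands", call. = FALSE)
    if (any(n_islands$at < 0 | n_islands$at > base_len))
      stop("island position outside the assembled length", call. = FALSE)
  }
  structure(list(blocks = blocks, n_islands = n_islands,
                 seed = as.integer(seed), id = id),
            class = "synthetic_genome_spec")
}

#' @export
print.synthetic_genome_spec <- function(x, ...) {
  cat(sprintf("<synthetic_genome_spec> %s: %d block(s), %s bp, %d island(s), seed %d\n",
              x$id, nrow(x$blocks), format(sum(x$blocks$length),
                                           big.mark = ","),
              if (is.null(x$n_islands)) 0L else nrow(x$n_islands), x$seed))
  invisible(x)
}

#' Generate a synthetic mosaic genome with known truth
#'
#' Builds the sequence described by a [synthetic_genome_spec()].  In
#' stochastic mode each base of a block is G or C independently with
#' probability `gc` (G vs C and A vs T equiprobable).  In exact mode each
#' block carries exactly `round(gc * length)` G/C bases placed
#' deterministically at evenly spaced positions, so block GC is bit-exact
#' and results are reproducible without sampling noise.  N islands are then
#' spliced in at their stated offsets.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param exact_gc Use exact mode (default `FALSE`).
#' @return List with `sequence` (a [gcd_sequence()]) and `truth` (tibble of
#'   0-based half-open intervals in final coordinates: `start`, `end`,
#'   `gc`, `type` = `"domain"` or `"n_island"`).
#' @examples
#' g <- generate_genome(synthetic_genome_spec(
#'   tibble::tibble(length = 100, gc = 0)), exact_gc = TRUE)
#' gc_fraction(g$sequence)  # 0
#' @export
generate_genome <- function(spec, exact_gc = FALSE) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  pieces <- vector("list", nrow(spec$blocks))
  for (i in seq_len(nrow(spec$blocks))) {
    pieces[[i]] <- make_block(spec$blocks$length[i], spec$blocks$gc[i],
                              exact_gc)
  }
  base_seq <- paste(unlist(pieces), collapse = "")
  base_ends <- cumsum(spec$blocks$length)
  truth <- tibble::tibble(start = base_ends - spec$blocks$length,
                          end = base_ends, gc = spec$blocks$gc,
                          type = "domain")

  if (!is.null(spec$n_islands) && nrow(spec$n_islands) > 0) {
    isl <- spec$n_islands
    # splice islands, rightmost first so earlier offsets stay valid
    out_seq <- base_seq
    for (j in rev(seq_len(nrow(isl)))) {
      at <- isl$at[j]
      out_seq <- paste0(substr(out_seq, 1, at),
                        strrep("N", isl$length[j]),
                        substr(out_seq, at + 1, nchar(out_seq)))
    }
    # translate truth to final coordinates, splitting blocks at insertions
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      cuts <- isl$at[isl$at > truth$start[i] & isl$at < truth$end[i]]
      edges <- c(truth$start[i], cuts, truth$end[i])
      for (k in seq_len(length(edges) - 1L)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          base_start = edges[k], base_end = edges[k + 1L],
          gc = truth$gc[i], type = "domain")
      }
    }
    parts <- dplyr::bind_rows(rows)
    # a part starting at base offset v lies after every island inserted at
    # or before v; its end shifts only by islands strictly before it
    shift_start <- function(x) vapply(x, function(v)
      v + sum(isl$length[isl$at <= v]), numeric(1))
    shift_end <- function(x) vapply(x, function(v)
      v + sum(isl$length[isl$at < v]), numeric(1))
    parts$start <- shift_start(parts$base_start)
    parts$end <- shift_end(parts$base_end)
    isl_final_start <- shift_end(isl$at)
    isl_rows <- tibble::tibble(start = isl_final_start,
                               end = isl_final_start + isl$length,
                               gc = 0, type = "n_island")
    truth <- dplyr::bind_rows(parts[, c("start", "end", "gc", "type")],
                              isl_rows)
    truth <- truth[order(truth$start), , drop = FALSE]
    base_seq <- out_seq
  }
  list(sequence = gcd_sequence(spec$id, base_seq), truth = truth)
}

make_block <- function(len, gc, exact_gc) {
  if (exact_gc) {
    k <- round(gc * len)
    # Bresenham-style even placement: position i is G/C when the running
    # count floor(i*k/len) increments
    i <- seq_len(len)
    is_gc <- floor(i * k / len) > floor((i - 1) * k / len)
    letters <- character(len)
    letters[is_gc] <- rep_len(c("G", "C"), sum(is_gc))
    letters[!is_gc] <- rep_len(c("A", "T"), len - sum(is_gc))
  } else {
    is_gc <- runif(len) < gc
    letters <- ifelse(is_gc,
                      ifelse(runif(len) < 0.5, "G", "C"),
                      ifelse(runif(len) < 0.5, "A", "T"))
  }
  paste(letters, collapse = "")
}

#' Write a truth table as BED
#'
#' @param truth Truth tibble from [generate_genome()].
#' @param path Output path.
#' @param source_id Chromosome name for the BED records.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path, source_id = "synthetic") {
  bed <- data.frame(chrom = source_id,
                    start = format(truth$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(truth$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("%s_gc%.4f", truth$type, truth$gc))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a truth BED written by [write_truth_bed()]
#'
#' @param path BED path.
#' @return Truth tibble (`start`, `end`, `gc`, `type`, `source_id`).
#' @export
read_truth_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  m <- regmatches(bed$name, regexec("^(domain|n_island)_gc([0-9.]+)$",
                                    bed$name))
  tibble::tibble(start = as.numeric(bed$start), end = as.numeric(bed$end),
                 gc = vapply(m, function(x) as.numeric(x[3]), numeric(1)),
                 type = vapply(m, `[[`, character(1), 2),
                 source_id = bed$chrom)
}

#' Score inferred domain boundaries against the truth
#'
#' Boundaries are the internal breakpoints of each tiling (sequence ends
#' excluded).  Matching is greedy nearest-pair: candidate pairs within
#' `tolerance` bp are taken in order of increasing distance (ties toward the
#' leftmost truth boundary), each boundary used at most once.
#'
#' @param truth Truth tibble from [generate_genome()] (0-based half-open).
#'   If it has a `source_id` column it must match the inferred table's.
#' @param inferred Domain records with 1-based inclusive `start`/`end`
#'   columns (pipeline output) and optionally `source_id`.
#' @param tolerance Maximum matching distance in bp.
#' @return One-row tibble: `precision` (matched / inferred), `recall`
#'   (matched / truth), `mean_offset` (mean absolute distance of matched
#'   pairs), `n_truth`, `n_inferred`, `n_matched`.
#' @export
score_boundaries <- function(truth, inferred, tolerance = 2000) {
  if ("source_id" %in% names(truth) && "source_id" %in% names(inferred)) {
    if (!identical(sort(unique(truth$source_id)),
                   sort(unique(inferred$source_id))))
      stop("truth and inferred tables refer to different source ids",
           call. = FALSE)
  }
  tb <- sort(unique(truth$end))
  tb <- tb[tb < max(truth$end)]              # internal breakpoints, 0-based
  ib <- sort(unique(inferred$end))
  ib <- ib[ib < max(inferred$end)]           # 1-based inclusive end == break
  pairs <- expand.grid(t = seq_along(tb), i = seq_along(ib))
  if (nrow(pairs) > 0) {
    pairs$dist <- abs(tb[pairs$t] - ib[pairs$i])
    pairs <- pairs[pairs$dist <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, tb[pairs$t]), , drop = FALSE]
  }
  used_t <- logical(length(tb)); used_i <- logical(length(ib))
  offsets <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    ti <- pairs$t[k]; ii <- pairs$i[k]
    if (used_t[ti] || used_i[ii]) next
    used_t[ti] <- TRUE; used_i[ii] <- TRUE
    offsets <- c(offsets, pairs$dist[k])
  }
  n_m <- sum(used_t)
  tibble::tibble(
    precision = if (length(ib)) n_m / length(ib) else NA_real_,
    recall = if (length(tb)) n_m / length(tb) else NA_real_,
    mean_offset = if (n_m) mean(offsets) else NA_real_,
    n_truth = length(tb), n_inferred = length(ib), n_matched = n_m)
}
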