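#' Map maximal N runs ("N islands") in a sequence
#'
#' Assembly gaps and ambiguous stretches appear as runs of `N`.  Segmentation
#' is performed on the sequence with those runs removed, and domain
#' coordinates are restored afterwards, so the first step is an exact map of
#' every maximal N run.
#'
#' @param seq A [gcd_sequence()].
#' @return A tibble with columns `start`, `end` (0-based half-open, original
#'   coordinates) and `length`; zero rows when the sequence has no N.
#'   Attributes `source_id` and `source_length` identify the host sequence.
#' @examples
#' map_n_islands(gcd_sequence("x", "NNACGNN"))
#' @export
map_n_islands <- function(seq) {
  is_n <- is.na(gc_indicator(seq))
  r <- rle(is_n)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  out <- tibble::tibble(start = as.numeric(starts[keep]),
                        end = as.numeric(ends[keep]))
  out$length <- out$end - out$start
  attr(out, "source_id") <- seq$id
  attr(out, "source_length") <- seq_length(seq)
  out
}

#' Remove N islands before segmentation
#'
#' Returns the sequence with every `N` removed, together with a coordinate
#' map that inverts the removal exactly: each kept (non-N) stretch is
#' recorded as a pair of intervals, one in stripped coordinates and one in
#' original coordinates.
#'
#' @param seq A [gcd_sequence()] with at least one non-N residue.
#' @return A list with elements `sequence` (the N-free [gcd_sequence()]) and
#'   `map` (tibble with columns `stripped_start`, `stripped_end`,
#'   `orig_start`, `orig_end`; stripped intervals tile the stripped length).
#' @examples
#' strip_ns(gcd_sequence("x", "ANNGT"))$sequence
#' @export
strip_ns <- function(seq) {
  ind <- gc_indicator(seq)
  keep <- !is.na(ind)
  if (!any(keep))
    stop(sprintf("sequence '%s' entirely N", seq$id), call. = FALSE)
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  ks <- as.numeric(starts[r$values])
  ke <- as.numeric(ends[r$values])
  lens <- ke - ks
  se <- cumsum(lens)
  map <- tibble::tibble(
    stripped_start = se - lens, stripped_end = se,
    orig_start = ks, orig_end = ke
  )
  chars <- strsplit(seq$seq, "")[[1L]]
  stripped <- gcd_sequence(seq$id, paste(chars[keep], collapse = ""))
  list(sequence = stripped, map = map)
}

#' Restore domain coordinates around N islands
#'
#' Maps a segmentation computed on the stripped (N-free) sequence back onto
#' original coordinates, applying the mask-or-split rule: an N island shorter
#' than `max_mask` that falls inside a domain is absorbed ("masked"), leaving
#' the domain contiguous; an island of length `>= max_mask` splits the domain
#' into a left part, a flagged N segment, and a right part.  An island
#' sitting exactly on a junction between two domains never extends either
#' side when large; when masked-size it is appended to the upstream (left)
#' domain (to the downstream domain at the very start of the sequence, where
#' no upstream domain exists).  Two distinct domains are never merged across
#' an island.
#'
#' @param domains Tibble of 0-based half-open intervals (`start`, `end`) in
#'   stripped coordinates; must tile the stripped sequence.
#' @param map Coordinate map from [strip_ns()].
#' @param islands N island map from [map_n_islands()] (carries the source
#'   length).
#' @param max_mask Mask threshold in bp (default 50000): islands strictly
#'   shorter are masked, islands at least this long split.
#' @return Tibble tiling `[0, source_length)` in original coordinates with
#'   columns `orig_start`, `orig_end`, `is_n_segment`, and for non-N rows
#'   the stripped subinterval they cover (`stripped_start`, `stripped_end`)
#'   plus the index `domain` of the stripped domain they derive from.
#' @export
restore_domains <- function(domains, map, islands, max_mask = 50000) {
  if (max_mask < 0) stop("max_mask must be >= 0", call. = FALSE)
  source_length <- attr(islands, "source_length")
  if (is.null(source_length))
    stop("islands must come from map_n_islands()", call. = FALSE)
  stripped_length <- sum(map$stripped_end - map$stripped_start)
  if (!tiles_exactly(domains$start, domains$end, stripped_length))
    stop("segmentation does not tile the stripped sequence", call. = FALSE)
  domains <- domains[order(domains$start), , drop = FALSE]

  # Atomize: split kept stretches at domain boundaries, interleave islands.
  atoms <- list()
  for (i in seq_len(nrow(domains))) {
    a <- domains$start[i]; b <- domains$end[i]
    hit <- map[map$stripped_end > a & map$stripped_start < b, , drop = FALSE]
    for (j in seq_len(nrow(hit))) {
      s0 <- max(a, hit$stripped_start[j]); s1 <- min(b, hit$stripped_end[j])
      off <- hit$orig_start[j] - hit$stripped_start[j]
      atoms[[length(atoms) + 1L]] <- list(
        orig_start = s0 + off, orig_end = s1 + off,
        stripped_start = s0, stripped_end = s1,
        domain = i, island = FALSE)
    }
  }
  for (j in seq_len(nrow(islands))) {
    atoms[[length(atoms) + 1L]] <- list(
      orig_start = islands$start[j], orig_end = islands$end[j],
      stripped_start = NA_real_, stripped_end = NA_real_,
      domain = NA_integer_, island = TRUE)
  }
  ord <- order(vapply(atoms, `[[`, numeric(1), "orig_start"))
  atoms <- atoms[ord]

  # Resolve each island: standalone N segment, or absorbed into a domain.
  dom_of <- vapply(atoms, `[[`, integer(1), "domain")
  is_isl <- vapply(atoms, `[[`, logical(1), "island")
  n <- length(atoms)
  key <- character(n)
  for (i in seq_len(n)) {
    if (!is_isl[i]) { key[i] <- paste0("D", dom_of[i]); next }
    len <- atoms[[i]]$orig_end - atoms[[i]]$orig_start
    prev_dom <- if (i > 1L) dom_of[max(which(!is_isl[seq_len(i - 1L)]), 0L)] else NA_integer_
    if (i == 1L || !any(!is_isl[seq_len(i - 1L)])) prev_dom <- NA_integer_
    nxt <- which(!is_isl & seq_len(n) > i)
    next_dom <- if (length(nxt)) dom_of[nxt[1L]] else NA_integer_
    if (len >= max_mask) {
      key[i] <- paste0("N", i)                    # standalone flagged segment
    } else if (!is.na(prev_dom)) {
      key[i] <- paste0("D", prev_dom)             # masked: upstream domain
      dom_of[i] <- prev_dom
    } else {
      key[i] <- paste0("D", next_dom)             # leading edge: downstream
      dom_of[i] <- next_dom
    }
  }

  # Group consecutive atoms with the same key into output segments; a large
  # island breaks its host domain into separate left/right parts naturally.
  grp <- cumsum(c(TRUE, key[-1L] != key[-n]))
  segs <- lapply(split(seq_len(n), grp), function(ii) {
    aa <- atoms[ii]
    kept <- !vapply(aa, `[[`, logical(1), "island") |
      !is.na(vapply(aa, `[[`, integer(1), "domain"))
    n_seg <- startsWith(key[ii[1L]], "N")
    ss <- vapply(aa, `[[`, numeric(1), "stripped_start")
    se <- vapply(aa, `[[`, numeric(1), "stripped_end")
    tibble::tibble(
      orig_start = aa[[1L]]$orig_start,
      orig_end = aa[[length(aa)]]$orig_end,
      is_n_segment = n_seg,
      stripped_start = if (n_seg) NA_real_ else min(ss, na.rm = TRUE),
      stripped_end = if (n_seg) NA_real_ else max(se, na.rm = TRUE),
      domain = if (n_seg) NA_integer_ else dom_of[ii[1L]]
    )
  })
  out <- dplyr::bind_rows(segs)
  out <- out[order(out$orig_start), , drop = FALSE]
  if (!tiles_exactly(out$orig_start, out$orig_end, source_length))
    stop("internal error: restored segments do not tile the source",
         call. = FALSE)
  out
}
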