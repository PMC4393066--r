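#' Genomic sequence container
#'
#' A minimal container for one named nucleotide sequence over the alphabet
#' `{A, C, G, T, N}`.  Lowercase residues are uppercased and every IUPAC
#' ambiguity code (R, Y, S, W, K, M, B, D, H, V) or other non-ACGTN symbol is
#' collapsed to `N`: such positions are either assembly gaps or polymorphic
#' bases, and both are treated identically downstream.
#'
#' @param id Sequence identifier (nonempty string; the FASTA header token).
#' @param residues A single string of residues; normalized on construction.
#' @return An object of class `gcd_sequence`: a list with elements `id`
#'   (string), `seq` (normalized residue string) and `remapped` (count of
#'   symbols collapsed to `N` during normalization).
#' @examples
#' s <- gcd_sequence("chr1", "acgRt")
#' seq_length(s)   # 5
#' seq_residues(s) # "ACGNT"
#' @export
gcd_sequence <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("sequence id must be a nonempty string", call. = FALSE)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("residues must be a single string", call. = FALSE)
  residues <- toupper(residues)
  n_acgtn <- nchar(residues) - nchar(gsub("[ACGTN]", "", residues))
  remapped <- nchar(residues) - n_acgtn
  if (remapped > 0L)
    residues <- gsub("[^ACGTN]", "N", residues)
  if (nchar(residues) < 1L)
    stop(sprintf("sequence '%s' has zero length", id), call. = FALSE)
  structure(list(id = id, seq = residues, remapped = remapped),
            class = "gcd_sequence")
}

#' @export
print.gcd_sequence <- function(x, ...) {
  n <- seq_length(x)
  preview <- substr(x$seq, 1L, min(n, 60L))
  if (n > 60L) preview <- paste0(preview, "...")
  cat(sprintf("<gcd_sequence> %s: %s bp, GC %.4f\n  %s\n",
              x$id, format(n, big.mark = ","), gc_fraction(x), preview))
  invisible(x)
}

#' Sequence length in base pairs
#' @param seq A [gcd_sequence()].
#' @return Integer length (bp).
#' @export
seq_length <- function(seq) nchar(seq$seq)

#' Residue string of a sequence
#' @param seq A [gcd_sequence()].
#' @return The normalized residue string.
#' @export
seq_residues <- function(seq) seq$seq

# GC indicator vector: 1 for G/C, 0 for A/T, NA for N.  The workhorse
# representation behind every GC statistic; computed once per sequence in
# hot paths and then reused via cumulative sums.
gc_indicator <- function(seq, start = 0, end = seq_length(seq)) {
  check_interval(start, end, seq_length(seq))
  r <- charToRaw(substr(seq$seq, start + 1L, end))
  lut <- rep(NA_integer_, 256L)
  lut[as.integer(charToRaw("A")) + 1L] <- 0L
  lut[as.integer(charToRaw("T")) + 1L] <- 0L
  lut[as.integer(charToRaw("G")) + 1L] <- 1L
  lut[as.integer(charToRaw("C")) + 1L] <- 1L
  lut[as.integer(r) + 1L]
}

#' Read genomic sequences from a FASTA file
#'
#' Reads a (possibly gzip-compressed, possibly multi-record) FASTA file and
#' returns one [gcd_sequence()] per record, in file order.  Residues are
#' normalized: lowercase is uppercased (soft-masked repeats are kept, not
#' removed) and every symbol outside `{A,C,G,T,N}` — including all IUPAC
#' ambiguity codes — is remapped to `N`.  The per-record count of remapped
#' symbols is reported with [message()] and kept in each object's
#' `remapped` field.
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @param quiet Suppress the per-record remapping messages.
#' @return Named list of `gcd_sequence` objects (names are record ids).
#' @export
read_genome_fasta <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop(sprintf("no sequences in %s", path), call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id '%s' in %s",
                 ids[duplicated(ids)][1L], path), call. = FALSE)
  widths <- Biostrings::width(set)
  if (any(widths == 0L))
    stop(sprintf("record '%s' has zero-length sequence",
                 ids[widths == 0L][1L]), call. = FALSE)
  out <- lapply(seq_along(set), function(i) {
    s <- gcd_sequence(ids[i], as.character(set[[i]]))
    if (!quiet && s$remapped > 0L)
      message(sprintf("%s: %d non-ACGTN symbol(s) remapped to N",
                      s$id, s$remapped))
    s
  })
  names(out) <- ids
  out
}

#' Write genomic sequences to a FASTA file
#'
#' @param seqs A `gcd_sequence` or list of them.
#' @param path Output path (`.gz` suffix compresses).
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "gcd_sequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, seq_residues, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  compress <- grepl("\\.gz$", path)
  Biostrings::writeXStringSet(set, path, format = "fasta",
                              width = width, compress = compress)
  invisible(path)
}

#' GC fraction of a sequence region
#'
#' Fraction of G+C residues over a 0-based half-open interval.  `N` residues
#' count in the denominator but never the numerator, so an all-N region has
#' GC 0.
#'
#' @param seq A [gcd_sequence()].
#' @param start,end 0-based half-open interval; defaults to the whole
#'   sequence.
#' @return A fraction in \[0, 1\].
#' @examples
#' gc_fraction(gcd_sequence("x", "ACGT"))          # 0.5
#' gc_fraction(gcd_sequence("x", "NNNNN"))         # 0
#' gc_fraction(gcd_sequence("x", "GGGCATAT"), 0, 8) # 0.5
#' @export
gc_fraction <- function(seq, start = 0, end = seq_length(seq)) {
  ind <- gc_indicator(seq, start, end)
  sum(ind == 1L, na.rm = TRUE) / (end - start)
}

#' Windowed GC series over a region
#'
#' GC fraction in consecutive non-overlapping windows of exactly `window` bp,
#' left to right across a region.  A trailing remainder shorter than the
#' window is discarded so that every value carries equal weight; the series
#' is the basis of the per-domain GC standard deviation and the homogeneity
#' test.
#'
#' @inheritParams gc_fraction
#' @param window Window size in bp (>= 1).
#' @return Numeric vector of per-window GC fractions (length >= 1).
#' @examples
#' windowed_gc(gcd_sequence("x", "GGGGAAAA"), window = 4)  # 1, 0
#' windowed_gc(gcd_sequence("x", "GGGGAAAAC"), window = 4) # remainder dropped
#' @export
windowed_gc <- function(seq, start = 0, end = seq_length(seq), window) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  check_interval(start, end, seq_length(seq))
  len <- end - start
  n_win <- floor(len / window)
  if (n_win < 1L)
    stop(sprintf("region too short for window (%d bp < %d bp)", len, window),
         call. = FALSE)
  ind <- gc_indicator(seq, start, start + n_win * window)
  ind[is.na(ind)] <- 0L
  cs <- c(0, cumsum(ind))
  edges <- seq(0L, n_win * window, by = window)
  diff(cs[edges + 1L]) / window
}
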