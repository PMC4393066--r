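#' Pipeline run configuration
#'
#' Bundles every tunable of the batch pipeline with its default.  All
#' settings are serialized into the run's metadata header so any output
#' table records the exact configuration that produced it.
#'
#' @param min_len Minimum domain length in bp (default 3000).
#' @param max_mask N islands shorter than this (bp) are masked inside
#'   domains; longer ones split them (default 50000).
#' @param window Window size in bp for the windowed GC series and
#'   homogeneity test (default 1024).
#' @param alpha Significance level of the homogeneity test (default 0.05).
#' @param isochoric_min,low_band,high_band,rich_cut Classification
#'   thresholds, see [classify_domains()].
#' @param model A `halting_model`, a path to one, or `NULL` for the shipped
#'   default.
#' @param seed Integer seed recorded with the run (the segmentation itself
#'   is deterministic).
#' @param plot Also write ideogram plots and sidecar tables.
#' @return A list of class `gcd_config`.
#' @export
gcd_config <- function(min_len = 3000, max_mask = 50000, window = 1024,
                       alpha = 0.05, isochoric_min = 300000,
                       low_band = c(0.20, 0.40), high_band = c(0.40, 0.60),
                       rich_cut = 0.3762, model = NULL, seed = 1,
                       plot = FALSE) {
  stopifnot(min_len > 0, max_mask >= 0, window > 0, alpha > 0, alpha < 1,
            isochoric_min > 0)
  structure(list(min_len = min_len, max_mask = max_mask, window = window,
                 alpha = alpha, isochoric_min = isochoric_min,
                 low_band = low_band, high_band = high_band,
                 rich_cut = rich_cut, model = model, seed = seed,
                 plot = plot),
            class = "gcd_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [gcd_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `gcd_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(gcd_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(gcd_config, vals)
}

resolve_model <- function(model) {
  if (is.null(model)) return(default_halting_model())
  if (inherits(model, "halting_model")) return(model)
  if (is.character(model)) return(read_halting_model(model))
  stop("model must be a halting_model, a path, or NULL", call. = FALSE)
}

#' Segment one sequence end to end
#'
#' The per-sequence pipeline: map N islands, strip them, segment the N-free
#' sequence, restore coordinates with the mask-or-split rule, compute GC
#' statistics and homogeneity verdicts over the non-N residues of each
#' restored segment, and classify.  GC statistics of a domain that absorbed
#' masked Ns are computed over its non-N residues only, while its reported
#' coordinates and length stay genomic.
#'
#' @param seq A [gcd_sequence()].
#' @param config A [gcd_config()].
#' @return Tibble of domain records with 1-based inclusive coordinates:
#'   `source_id`, `start`, `end`, `length`, `gc`, `gc_std`, `homogeneity`,
#'   `is_n_segment`, `size_class`, `gc_band`, `rich_class`.
#' @export
segment_genome <- function(seq, config = gcd_config()) {
  model <- resolve_model(config$model)
  islands <- map_n_islands(seq)
  n_total <- sum(islands$length)

  if (n_total == seq_length(seq)) {
    # entirely N: one flagged segment, nothing to segment
    restored <- tibble::tibble(orig_start = 0,
                               orig_end = as.numeric(seq_length(seq)),
                               is_n_segment = TRUE,
                               stripped_start = NA_real_,
                               stripped_end = NA_real_, domain = NA_integer_)
    stripped_seq <- NULL
  } else {
    st <- strip_ns(seq)
    stripped_seq <- st$sequence
    doms <- segment_sequence(stripped_seq, model, min_len = config$min_len)
    restored <- restore_domains(doms, st$map, islands,
                                max_mask = config$max_mask)
  }

  n <- nrow(restored)
  gc <- numeric(n); gc_std <- rep(NA_real_, n); hom <- rep(NA_real_, n)
  if (!is.null(stripped_seq)) {
    chrom_gc <- if (seq_length(stripped_seq) >= 2 * config$window)
      windowed_gc(stripped_seq, window = config$window) else numeric(0)
    for (i in seq_len(n)) {
      if (restored$is_n_segment[i]) next
      a <- restored$stripped_start[i]; b <- restored$stripped_end[i]
      gc[i] <- gc_fraction(stripped_seq, a, b)
      dom_gc <- if (b - a >= config$window)
        windowed_gc(stripped_seq, a, b, window = config$window)
      else numeric(0)
      if (length(dom_gc) >= 2L) gc_std[i] <- sd(dom_gc)
      v <- test_homogeneity_or_default(dom_gc, chrom_gc, config$alpha)
      hom[i] <- as.numeric(v$is_homogeneous)
    }
  }
  records <- tibble::tibble(
    source_id = seq$id,
    start = restored$orig_start + 1,       # 1-based inclusive for reporting
    end = restored$orig_end,
    length = restored$orig_end - restored$orig_start,
    gc = gc, gc_std = gc_std, homogeneity = hom,
    is_n_segment = restored$is_n_segment
  )
  classify_domains(records, isochoric_min = config$isochoric_min,
                   low_band = config$low_band, high_band = config$high_band,
                   rich_cut = config$rich_cut)
}

#' Run the batch segmentation pipeline over a directory of FASTA files
#'
#' For every sequence in every FASTA file under `input_dir`:
#' read, map and strip N islands, segment, test homogeneity, restore
#' coordinates, classify, and append the records to one run-level
#' `seg_no_ns.txt` TSV.  Also writes a per-class coverage summary, a plain
#' text log with per-sequence timing and remapped-symbol counts, and,
#' when `config$plot` is set, ideogram plots with sidecar tables.  Output
#' is deterministic given the configuration and halting model.
#'
#' @param input_dir Directory holding `.fa`/`.fasta`/`.fna` files
#'   (optionally gzipped); at least one required.
#' @param output_dir Output directory (created if needed; must differ from
#'   `input_dir`).
#' @param config A [gcd_config()].
#' @return Invisibly, a list with `records` (the combined tibble),
#'   `coverage`, `status` (0 on full success, 1 when any file was skipped),
#'   and output `paths`.  Unreadable files are skipped with a logged error
#'   and reflected in the status.
#' @export
run_pipeline <- function(input_dir, output_dir, config = gcd_config()) {
  if (!dir.exists(input_dir))
    stop(sprintf("input directory not found: %s", input_dir), call. = FALSE)
  if (normalizePath(input_dir) ==
      normalizePath(output_dir, mustWork = FALSE))
    stop("input and output directories must differ", call. = FALSE)
  files <- sort(list.files(input_dir,
                           pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no FASTA files in %s", input_dir), call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  log_lines <- c(sprintf("gcdomains run %s", format(Sys.time())),
                 config_header(config))
  all_records <- list()
  status <- 0L
  for (f in files) {
    seqs <- tryCatch(read_genome_fasta(f, quiet = TRUE), error = function(e) {
      log_lines <<- c(log_lines,
                      sprintf("ERROR %s: %s", basename(f),
                              conditionMessage(e)))
      status <<- 1L
      NULL
    })
    if (is.null(seqs)) next
    for (s in seqs) {
      if (seq_length(s) < 10 * config$min_len)
        log_lines <- c(log_lines, sprintf(
          "WARNING %s: record is shorter than 10 x min_len (%d bp); %s",
          s$id, seq_length(s),
          "short-domain calls on scaffolds this size are unreliable"))
      t0 <- proc.time()[["elapsed"]]
      recs <- withCallingHandlers(
        segment_genome(s, config),
        warning = function(w) {
          log_lines <<- c(log_lines, sprintf("WARNING %s: %s", s$id,
                                             conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      elapsed <- proc.time()[["elapsed"]] - t0
      log_lines <- c(log_lines, sprintf(
        "%s: %d bp, %d remapped symbol(s), %d segment(s), %.2f s",
        s$id, seq_length(s), s$remapped, nrow(recs), elapsed))
      all_records[[length(all_records) + 1L]] <- recs
    }
  }
  records <- dplyr::bind_rows(all_records)

  paths <- list(
    segments = file.path(output_dir, "seg_no_ns.txt"),
    coverage = file.path(output_dir, "coverage_summary.txt"),
    log = file.path(output_dir, "pipeline.log")
  )
  write_records_tsv(records, paths$segments, config)
  coverage <- coverage_summary(records, by = "size_class")
  write_records_tsv(coverage, paths$coverage, config)
  if (isTRUE(config$plot) && nrow(records) > 0)
    paths$plots <- save_ideograms(records, output_dir)
  writeLines(log_lines, paths$log)
  invisible(list(records = records, coverage = coverage, status = status,
                 paths = paths))
}

config_header <- function(config) {
  scalar <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                              collapse = ",")
  model_lab <- if (is.character(config$model)) config$model
  else if (inherits(config$model, "halting_model")) "in-memory"
  else "default"
  c(sprintf("# min_len: %s", scalar(config$min_len)),
    sprintf("# max_mask: %s", scalar(config$max_mask)),
    sprintf("# window: %s", scalar(config$window)),
    sprintf("# alpha: %s", scalar(config$alpha)),
    sprintf("# isochoric_min: %s", scalar(config$isochoric_min)),
    sprintf("# low_band: %s", scalar(config$low_band)),
    sprintf("# high_band: %s", scalar(config$high_band)),
    sprintf("# rich_cut: %s", scalar(config$rich_cut)),
    sprintf("# model: %s", model_lab),
    sprintf("# seed: %s", scalar(config$seed)))
}

write_records_tsv <- function(records, path, config) {
  writeLines(config_header(config), path)
  readr::write_tsv(records, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a pipeline segments or coverage table back
#'
#' @param path A TSV written by [run_pipeline()] (metadata header lines
#'   start with `#`).
#' @return A tibble.
#' @export
read_records_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Validate that pipeline output tiles its sources
#'
#' Checks, per source sequence, that the records cover `[1, max(end)]`
#' with no gaps or overlaps and that lengths are consistent with the
#' coordinates.
#'
#' @param records Domain records (tibble or path to a pipeline TSV).
#' @return `TRUE` invisibly; errors with the offending source otherwise.
#' @export
check_tiling <- function(records) {
  if (is.character(records)) records <- read_records_tsv(records)
  for (sid in unique(records$source_id)) {
    r <- records[records$source_id == sid, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    ok <- min(r$start) == 1 &&
      all(r$end - r$start + 1 == r$length) &&
      tiles_exactly(r$start - 1, r$end, max(r$end))
    if (!ok)
      stop(sprintf("records do not tile source '%s'", sid), call. = FALSE)
  }
  invisible(TRUE)
}
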