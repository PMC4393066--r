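#' Classify restored domains by size, GC band and GC richness
#'
#' Assigns three categorical labels to each domain record:
#'
#' * `size_class`: `"isochoric"` when the domain is longer than
#'   `isochoric_min` bp *and* homogeneous (long homogeneous domains are the
#'   classical isochores), otherwise `"short"`.
#' * `gc_band`: `"low"` for GC in `[low_band[1], low_band[2])`, `"high"`
#'   for GC in `[high_band[1], high_band[2])`, `"other"` outside both
#'   (half-open bands make the shared 40% edge unambiguous; e.g. a 61% GC
#'   domain falls outside both bands).
#' * `rich_class`: `"GC-rich"` when GC exceeds `rich_cut` (default 37.62%,
#'   the mean GC content across insect genomes), else `"GC-poor"`.
#'
#' Flagged N segments receive `NA` for all three labels and form their own
#' stratum in coverage summaries.
#'
#' @param records Tibble of domain records carrying `length`, `gc`,
#'   `homogeneity` and (optionally) `is_n_segment` columns.
#' @param isochoric_min Minimum isochoric length in bp (strict `>`;
#'   default 300000).
#' @param low_band,high_band Two-element numeric vectors giving half-open
#'   GC bands (defaults `[0.20, 0.40)` and `[0.40, 0.60)`).
#' @param rich_cut GC fraction above which a domain is GC-rich (strict `>`;
#'   default 0.3762).
#' @return `records` with `size_class`, `gc_band` and `rich_class` columns.
#' @examples
#' classify_domains(tibble::tibble(length = c(300001, 300000),
#'                                 gc = c(0.35, 0.61),
#'                                 homogeneity = c(1, 1)))
#' @export
classify_domains <- function(records, isochoric_min = 300000,
                             low_band = c(0.20, 0.40),
                             high_band = c(0.40, 0.60),
                             rich_cut = 0.3762) {
  n_seg <- if ("is_n_segment" %in% names(records)) records$is_n_segment
           else rep(FALSE, nrow(records))
  iso <- records$length > isochoric_min &
    !is.na(records$homogeneity) & records$homogeneity == 1
  size_class <- ifelse(iso, "isochoric", "short")
  gc_band <- dplyr::case_when(
    records$gc >= low_band[1] & records$gc < low_band[2] ~ "low",
    records$gc >= high_band[1] & records$gc < high_band[2] ~ "high",
    TRUE ~ "other"
  )
  rich_class <- ifelse(records$gc > rich_cut, "GC-rich", "GC-poor")
  records$size_class <- ifelse(n_seg, NA_character_, size_class)
  records$gc_band <- ifelse(n_seg, NA_character_, gc_band)
  records$rich_class <- ifelse(n_seg, NA_character_, rich_class)
  records
}

#' Genome coverage per domain class
#'
#' Sums base pairs and genome fraction per class level, per source sequence
#' and over all sources pooled (`source_id == "all"`).  Records must tile
#' each source; N segments (class `NA`) are reported as their own
#' `"n_island"` stratum so fractions sum to 1 per source.
#'
#' @param records Domain records with 1-based inclusive `start`/`end`,
#'   `length`, `source_id` and the grouping column.
#' @param by Name of the class column to summarize (default
#'   `"size_class"`).
#' @return Tibble with columns `source_id`, `class`, `bp`, `fraction`.
#' @export
coverage_summary <- function(records, by = "size_class") {
  if (!by %in% names(records))
    stop(sprintf("no column '%s' in records", by), call. = FALSE)
  for (sid in unique(records$source_id)) {
    r <- records[records$source_id == sid, , drop = FALSE]
    if (!tiles_exactly(r$start - 1, r$end, max(r$end)) || min(r$start) != 1)
      stop(sprintf("records do not tile source '%s'", sid), call. = FALSE)
  }
  cls <- records[[by]]
  cls[is.na(cls)] <- "n_island"
  per <- records |>
    dplyr::mutate(class = cls) |>
    dplyr::group_by(.data$source_id, .data$class) |>
    dplyr::summarise(bp = sum(.data$length), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$bp / sum(.data$bp)) |>
    dplyr::ungroup()
  total <- per |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop") |>
    dplyr::mutate(source_id = "all", fraction = .data$bp / sum(.data$bp))
  dplyr::bind_rows(per, total[, names(per)])
}

#' Coverage by GC richness and length bin
#'
#' Cross-tabulates genome coverage by `rich_class` and a binned domain
#' length, the layout used to compare compositional organization across
#' genomes.  Default bins follow the scale at which short-domain artifacts
#' matter in scaffold assemblies: under 10 kb, 10–100 kb, over 100 kb.
#'
#' @param records Domain records (see [coverage_summary()]).
#' @param length_bins Increasing numeric break points (bp), implicitly
#'   starting at 0 and ending at `Inf`.
#' @return Tibble with `source_id`, `rich_class`, `length_bin`, `bp`,
#'   `fraction` (fractions sum to 1 per source over non-N records).
#' @export
coverage_matrix <- function(records, length_bins = c(1e4, 1e5)) {
  breaks <- c(0, sort(length_bins), Inf)
  labs <- character(length(breaks) - 1L)
  for (i in seq_along(labs)) {
    labs[i] <- if (i == 1L) sprintf("<%s", fmt_bp(breaks[2L]))
    else if (i == length(labs)) sprintf(">%s", fmt_bp(breaks[i]))
    else sprintf("%s-%s", fmt_bp(breaks[i]), fmt_bp(breaks[i + 1L]))
  }
  r <- records[is.na(records$is_n_segment) | !records$is_n_segment, ,
               drop = FALSE]
  r$length_bin <- cut(r$length, breaks = breaks, labels = labs,
                      right = FALSE)
  r |>
    dplyr::group_by(.data$source_id, .data$rich_class, .data$length_bin,
                    .drop = FALSE) |>
    dplyr::summarise(bp = sum(.data$length), .groups = "drop") |>
    dplyr::group_by(.data$source_id) |>
    dplyr::mutate(fraction = .data$bp / sum(.data$bp)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$rich_class))
}

fmt_bp <- function(x) {
  if (x >= 1e6) sprintf("%gMb", x / 1e6)
  else if (x >= 1e3) sprintf("%gkb", x / 1e3)
  else sprintf("%gbp", x)
}
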