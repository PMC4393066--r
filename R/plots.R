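# Graphics: ideogram layers, length distributions, coverage matrices.
# Every plot is built from a plain table that can also be written as a
# sidecar TSV, so figures are regenerable from the sidecars alone.

scales_bp <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x >= 1e6, sprintf("%g Mb", x / 1e6),
                ifelse(x >= 1e3, sprintf("%g kb", x / 1e3),
                       sprintf("%g bp", x))))
}

ideogram_layers <- c("homogeneity", "size", "gc_band")

ideogram_data <- function(records, layer = ideogram_layers) {
  layer <- match.arg(layer)
  lab <- switch(layer,
    homogeneity = dplyr::case_when(
      records$is_n_segment ~ "N island",
      records$homogeneity == 1 ~ "homogeneous",
      TRUE ~ "nonhomogeneous"),
    size = dplyr::case_when(
      records$is_n_segment ~ "N island",
      records$size_class == "isochoric" ~ "isochoric",
      records$homogeneity == 1 ~ "short homogeneous",
      TRUE ~ "nonhomogeneous"),
    gc_band = dplyr::case_when(
      records$is_n_segment ~ "N island",
      records$size_class != "isochoric" ~ "non-isochoric",
      records$gc_band == "low" ~ "isochoric, low GC (20-40%)",
      records$gc_band == "high" ~ "isochoric, high GC (40-60%)",
      TRUE ~ "isochoric, other GC")
  )
  tibble::tibble(source_id = records$source_id, start = records$start,
                 end = records$end, class = lab)
}

ideogram_palette <- list(
  homogeneity = c("homogeneous" = "#2166ac", "nonhomogeneous" = "#b2182b",
                  "N island" = "grey70"),
  size = c("isochoric" = "#1b7837", "short homogeneous" = "#a6dba0",
           "nonhomogeneous" = "#c2a5cf", "N island" = "grey70"),
  gc_band = c("isochoric, low GC (20-40%)" = "#d73027",
              "isochoric, high GC (40-60%)" = "#4575b4",
              "isochoric, other GC" = "#fee090",
              "non-isochoric" = "grey88", "N island" = "grey60")
)

#' Ideogram of compositional domains
#'
#' Draws each source sequence as a horizontal bar scaled to base pairs and
#' paints its domains by one of three layers: `"homogeneity"` (homogeneous
#' vs nonhomogeneous), `"size"` (isochoric vs short-homogeneous vs
#' nonhomogeneous) or `"gc_band"` (isochoric domains colored by GC band,
#' everything else muted).  N islands are shown in grey in every layer.
#'
#' @param records Domain records from [run_pipeline()] /
#'   [segment_genome()].
#' @param layer One of `"homogeneity"`, `"size"`, `"gc_band"`.
#' @return A ggplot.
#' @export
plot_ideogram <- function(records, layer = ideogram_layers) {
  if (nrow(records) == 0L) stop("no records to plot", call. = FALSE)
  layer <- match.arg(layer)
  d <- ideogram_data(records, layer)
  d$source_id <- factor(d$source_id, levels = rev(unique(d$source_id)))
  pal <- ideogram_palette[[layer]]
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start - 1, xmax = .data$end,
      ymin = as.integer(.data$source_id) - 0.4,
      ymax = as.integer(.data$source_id) + 0.4,
      fill = .data$class)) +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(d$source_id)),
                                labels = levels(d$source_id)) +
    ggplot2::scale_x_continuous(labels = scales_bp) +
    ggplot2::scale_fill_manual(values = pal, drop = TRUE) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = NULL,
                  title = sprintf("Compositional domains: %s layer",
                                  layer)) +
    ggplot2::theme_minimal()
}

#' Write the three ideogram layers as images with sidecar tables
#'
#' @param records Domain records.
#' @param out_dir Output directory.
#' @param formats Image formats, `"png"` and/or `"tiff"`.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Character vector of files written, invisibly.
#' @export
save_ideograms <- function(records, out_dir, formats = "png",
                           width = 9, height = 5, dpi = 150) {
  if (nrow(records) == 0L) stop("no records to plot", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (layer in ideogram_layers) {
    side <- file.path(out_dir, sprintf("ideogram_%s.tsv", layer))
    readr::write_tsv(ideogram_data(records, layer), side)
    written <- c(written, side)
    p <- plot_ideogram(records, layer)
    for (fmt in formats) {
      img <- file.path(out_dir, sprintf("ideogram_%s.%s", layer, fmt))
      ggplot2::ggsave(img, p, width = width, height = height, dpi = dpi)
      written <- c(written, img)
    }
  }
  invisible(written)
}

#' Domain length distribution
#'
#' Log-scaled histogram of domain lengths, optionally overlaid per source
#' (or any other grouping column), for comparing domain-size spectra
#' between genomes or builds.
#'
#' @param records Domain records (N segments are excluded).
#' @param bins Number of histogram bins.
#' @param by Optional grouping column name for overlaid series (e.g.
#'   `"source_id"`).
#' @return A ggplot.
#' @export
plot_length_distribution <- function(records, bins = 30, by = NULL) {
  if (nrow(records) == 0L) stop("no records to plot", call. = FALSE)
  d <- records[is.na(records$is_n_segment) | !records$is_n_segment, ,
               drop = FALSE]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$length))
  if (!is.null(by)) {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data[[by]]), bins = bins, alpha = 0.6,
      position = "identity")
  } else {
    p <- p + ggplot2::geom_histogram(bins = bins, fill = "#2166ac")
  }
  p + ggplot2::scale_x_log10(labels = scales_bp) +
    ggplot2::labs(x = "domain length (bp)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Coverage by GC richness and domain length bin
#'
#' Bar chart of the genome fraction covered by GC-poor vs GC-rich domains
#' within length bins, per source; the chart data come from
#' [coverage_matrix()] and match it exactly.
#'
#' @param records Domain records, or a precomputed [coverage_matrix()]
#'   tibble.
#' @param length_bins Passed to [coverage_matrix()] when `records` are raw
#'   domain records.
#' @return A ggplot.
#' @export
plot_coverage_matrix <- function(records, length_bins = c(1e4, 1e5)) {
  d <- if (all(c("length_bin", "fraction") %in% names(records))) records
  else coverage_matrix(records, length_bins)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length_bin,
                                  y = .data$fraction,
                                  fill = .data$rich_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~source_id) +
    ggplot2::scale_fill_manual(values = c("GC-poor" = "#d73027",
                                          "GC-rich" = "#4575b4")) +
    ggplot2::labs(x = "domain length", y = "genome fraction", fill = NULL) +
    ggplot2::theme_minimal()
}
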