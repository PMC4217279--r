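#' Plot a coverage profile
#'
#' Line plot of per-position coverage, faceted by strand when the profile
#' was computed with separate strands. TSS positions can be overlaid.
#'
#' @param profile tibble from [coverage_profile()] or [combine_tracks()].
#' @param tss optional tibble from [detect_tss()]; detected positions are
#'   marked.
#' @return a ggplot.
#' @export
plot_coverage <- function(profile, tss = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$pos,
                                             y = .data$coverage)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "position (bp)", y = "coverage") +
    ggplot2::theme_minimal()
  if (length(unique(profile$strand)) > 1) {
    p <- p + ggplot2::facet_wrap(~strand, ncol = 1)
  }
  if (!is.null(tss) && nrow(tss) > 0) {
    p <- p + ggplot2::geom_vline(data = tss,
                                 ggplot2::aes(xintercept = .data$position),
                                 colour = "firebrick", linetype = 3)
  }
  p
}

#' Plot per-class coverage of a track
#'
#' Draws the cumulative Perfect / Best / Common coverage of an interval;
#' by construction the three curves nest.
#'
#' @param track classified mapping tibble.
#' @inheritParams coverage_profile
#' @return a ggplot.
#' @export
plot_class_coverage <- function(track, genome = NULL, contig = NULL,
                                from = 1, to = NULL) {
  profs <- purrr::map_dfr(MAPPING_CLASSES, function(cl) {
    coverage_profile(track, genome, contig, from, to, class_filter = cl) |>
      mutate(class = cl)
  })
  profs$class <- factor(profs$class, levels = MAPPING_CLASSES)
  ggplot2::ggplot(profs, ggplot2::aes(x = .data$pos, y = .data$coverage,
                                      colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(PERFECT = "forestgreen",
                                            BEST = "goldenrod",
                                            COMMON = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = "coverage",
                  colour = "mapping class") +
    ggplot2::theme_minimal()
}
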