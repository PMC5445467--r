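#' Plot a coverage profile
#'
#' Per-base depth along each replicon, with the replicon median drawn as a
#' dashed line; coverage-deletion candidate regions show up as dropouts.
#'
#' @param coverage tibble from [coverage_profile()].
#' @param bin bin width (bp) for display averaging.
#' @return a ggplot object.
#' @export
plot_coverage <- function(coverage, bin = 100) {
  binned <- coverage |>
    mutate(bin = (.data$pos %/% bin) * bin) |>
    group_by(.data$replicon, .data$bin) |>
    summarise(depth = mean(.data$depth), .groups = "drop")
  med <- coverage |>
    group_by(.data$replicon) |>
    summarise(med = median(.data$depth), .groups = "drop")
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = med,
                        ggplot2::aes(yintercept = .data$med),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~replicon, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "depth") +
    ggplot2::theme_minimal()
}

#' Plot a placement graph
#'
#' Draws each contig's alignment edges as segments connecting contig
#' coordinates (top track) to reference coordinates (bottom track), one
#' panel per contig; mobile-element edges are coloured by label. Junction
#' topology — two edges for a novel insertion, four across the two junction
#' contigs of a mobile-element insertion — is visible directly.
#'
#' @param object a `placement_graph`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.placement_graph <- function(object, ...) {
  e <- object$edges
  if (nrow(e) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no edges") +
             ggplot2::theme_void())
  }
  seg <- bind_rows(
    mutate(e, x = .data$c_start, xend = .data$c_end, y = 1, yend = 1,
           track = "contig"),
    mutate(e, x = .data$r_start, xend = .data$r_end, y = 0, yend = 0,
           track = "reference"))
  links <- bind_rows(
    mutate(e, x = .data$c_start, xend = .data$r_start, y = 1, yend = 0),
    mutate(e, x = .data$c_end, xend = .data$r_end, y = 1, yend = 0))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$element),
      linewidth = 2) +
    ggplot2::geom_segment(
      data = links,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend),
      linetype = "dotted", linewidth = 0.3) +
    ggplot2::facet_wrap(~contig_id, scales = "free_x") +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("reference", "contig")) +
    ggplot2::labs(x = "coordinate (bp)", y = NULL, colour = "element") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot GT_TYPE evidence across samples
#'
#' Variant-by-sample heat tiles of the wild-type / marginal / mutant
#' trichotomy, the visual core of cross-sample variant triage.
#'
#' @param table evidence tibble from [build_evidence_table()].
#' @return a ggplot object.
#' @export
plot_gt_heatmap <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$SAMPLE_ID,
                               y = factor(.data$UID),
                               fill = factor(.data$GT_TYPE,
                                             levels = c(0, 1, 2)))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey85", `1` = "goldenrod", `2` = "firebrick"),
      drop = FALSE) +
    ggplot2::labs(x = "sample", y = "variant", fill = "GT_TYPE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
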