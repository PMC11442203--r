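#' Similarity heatmap
#'
#' Tile heatmap of a compound similarity (or distance) matrix, rows and
#' columns in dendrogram leaf order when one is supplied.
#'
#' @param S Square matrix with dimnames.
#' @param dend Optional `cfp_dendrogram` supplying the leaf order.
#' @param value Legend label.
#' @return A ggplot.
#' @export
plot_similarity_heatmap <- function(S, dend = NULL, value = "similarity") {
  ord <- if (!is.null(dend)) dend$hc$labels[dend$hc$order] else rownames(S)
  long <- matrix_to_long(S, value = "val") |>
    dplyr::mutate(x = factor(.data$x, levels = ord),
                  y = factor(.data$y, levels = rev(ord)))
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, fill = .data$val)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value, limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Coverage bar chart
#'
#' Per-indication bars for the four coverage ratios and the combined
#' ratio.
#'
#' @param coverage Tibble from [coverage_report()].
#' @return A ggplot.
#' @export
plot_coverage <- function(coverage) {
  long <- coverage |>
    dplyr::select("indication_id", "atc_coverage", "go_term_coverage",
                  "drug_coverage", "group_coverage", "combined_ratio") |>
    tidyr::pivot_longer(-"indication_id", names_to = "statistic", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(.data$indication_id, .data$ratio,
                                     fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "indication", y = "coverage ratio", fill = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Direction-call tile plot
#'
#' Group-by-term tiles showing the overall regulation direction
#' (up/down/flat) of each drug cluster group on each common process.
#'
#' @param group_calls `group_calls` tibble from [direction_report()].
#' @return A ggplot.
#' @export
plot_direction <- function(group_calls) {
  ggplot2::ggplot(group_calls,
                  ggplot2::aes(factor(.data$group), .data$term_id,
                               fill = .data$direction)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(up = "#b2182b", down = "#2166ac",
                                          flat = "grey70", no_call = "grey95")) +
    ggplot2::labs(x = "drug cluster group", y = "biological process",
                  fill = "direction") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.cfp_run <- function(object, ...) plot_coverage(object$coverage)

#' @exportS3Method ggplot2::autoplot
autoplot.cfp_dendrogram <- function(object, ...) {
  seg <- stats::as.dendrogram(object$hc)
  dd <- ggdend_segments(seg)$segments
  labs <- tibble::tibble(label = object$hc$labels[object$hc$order],
                         x = seq_along(object$hc$order))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dd, ggplot2::aes(x = .data$x, y = .data$y,
                                                  xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = labs, ggplot2::aes(.data$x, -0.02, label = .data$label),
                       angle = 90, hjust = 1, size = 2.5) +
    ggplot2::scale_y_continuous("merge height") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(plot.margin = ggplot2::margin(5, 5, 60, 5))
}

# Flatten a stats::dendrogram into segment coordinates for ggplot.
ggdend_segments <- function(node, x_offset = 0) {
  if (stats::is.leaf(node)) {
    return(list(segments = tibble::tibble(), center = x_offset + 1, width = 1))
  }
  left <- ggdend_segments(node[[1]], x_offset)
  right <- ggdend_segments(node[[2]], x_offset + left$width)
  h <- attr(node, "height")
  hl <- attr(node[[1]], "height")
  hr <- attr(node[[2]], "height")
  segs <- dplyr::bind_rows(
    left$segments, right$segments,
    tibble::tibble(x = left$center, xend = right$center, y = h, yend = h),
    tibble::tibble(x = left$center, xend = left$center, y = h, yend = hl),
    tibble::tibble(x = right$center, xend = right$center, y = h, yend = hr)
  )
  list(segments = segs, center = (left$center + right$center) / 2,
       width = left$width + right$width)
}
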