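# ggplot2 views of record tibbles and locate results.

#' Histogram of record lengths
#'
#' @param x a record tibble.
#' @param bins number of histogram bins.
#' @return a ggplot object.
#' @export
plot_length_hist <- function(x, bins = 30L) {
  check_fastx(x)
  df <- tibble::tibble(length = nchar(x$seq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "record length (bases)", y = "records") +
    ggplot2::theme_minimal()
}

#' GC content per record
#'
#' @param x a record tibble.
#' @return a ggplot object (GC% against record length).
#' @export
plot_gc_content <- function(x) {
  check_fastx(x)
  df <- tibble::tibble(length = nchar(x$seq), gc = gc_percent(x$seq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$gc)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = "record length (bases)", y = "GC content (%)") +
    ggplot2::theme_minimal()
}

#' Plot motif hits along their records
#'
#' @param object a hit tibble from [fastx_locate()].
#' @param ... unused.
#' @return a ggplot object: one horizontal lane per record, hits drawn as
#'   strand-coloured segments.
#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot fastx_hits
autoplot.fastx_hits <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$start, xend = .data$end,
    y = .data$seq_id, yend = .data$seq_id, colour = .data$strand
  )) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "position (bases)", y = NULL, colour = "strand") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
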