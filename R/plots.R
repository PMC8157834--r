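#' Plot octave histograms
#'
#' One panel per sample, bars over log2 abundance bins labelled with the
#' bin's lower edge (`2^k`).
#'
#' @param object An [octave_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.asv_octave <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$bin), y = .data$n_features)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "abundance bin (log2, lower edge = 2^k)",
                  y = "features") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot crosstalk filtering diagnostics
#'
#' Per-feature expected leak against total count, with point size showing
#' how many entries the filter zeroed; skipped features are marked.
#'
#' @param object An `asv_crosstalk` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.asv_crosstalk <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$total > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total, y = .data$expected_leak)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$entries_zeroed,
                                     shape = .data$skipped), alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "feature total count", y = "expected per-sample leak") +
    ggplot2::theme_minimal()
}

#' Convenience wrapper: octave plot straight from a feature table
#'
#' @param tbl Feature table tibble.
#' @return A ggplot object.
#' @export
plot_octave <- function(tbl) {
  autoplot(octave_summary(tbl))
}
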