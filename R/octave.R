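# Exact log2 binning: a count c >= 1 falls in bin k iff 2^k <= c < 2^(k+1).
# Computed by integer comparison against exact powers of two (binary search
# via findInterval), never via floating-point log.
octave_bin <- function(counts) {
  stopifnot(all(counts >= 1L))
  findInterval(counts, 2^(0:31)) - 1L
}

#' Octave histogram of one sample's feature abundances
#'
#' An octave plot bins per-sample feature counts by powers of two: bin `k`
#' holds the number of features whose count lies in `[2^k, 2^(k+1))`.
#' Zero counts are excluded, so the bin totals sum to the number of features
#' detected in the sample. The shape of the histogram is a quick quality
#' read-out for an amplicon run — a healthy sample shows a broad abundance
#' distribution, while a sample dominated by singletons (a spike at bin 0)
#' is a candidate for exclusion.
#'
#' @param tbl Feature table tibble.
#' @param sample_id Sample to summarize (must be a column of `tbl`).
#' @return Tibble with columns `sample_id`, `bin`, `low_edge`, `high_edge`
#'   (`[2^k, 2^(k+1) - 1]`, inclusive) and `n_features`; only occupied bins
#'   are listed, sorted by bin.
#' @examples
#' tbl <- feature_table(matrix(c(1L, 2L, 3L, 4L, 7L, 8L, 1024L), 7))
#' octave_histogram(tbl, "S1")
#' @export
octave_histogram <- function(tbl, sample_id) {
  tbl <- validate_feature_table(tbl)
  if (!sample_id %in% ft_sample_ids(tbl)) {
    stop_consistency(sprintf("sample '%s' not found in the table", sample_id))
  }
  counts <- tbl[[sample_id]]
  counts <- counts[counts > 0L]
  if (length(counts) == 0) {
    return(tibble(sample_id = character(), bin = integer(),
                  low_edge = double(), high_edge = double(),
                  n_features = integer()))
  }
  tab <- table(octave_bin(counts))
  k <- as.integer(names(tab))
  tibble(sample_id = sample_id, bin = k, low_edge = 2^k,
         high_edge = 2^(k + 1) - 1, n_features = as.integer(tab))
}

#' Octave histograms for every sample, in tidy long format
#'
#' @param tbl Feature table tibble.
#' @return A tibble of class `asv_octave` with one row per occupied
#'   (sample, bin) pair, sorted by sample then bin; columns as in
#'   [octave_histogram()]. Plot with [ggplot2::autoplot()].
#' @export
octave_summary <- function(tbl) {
  tbl <- validate_feature_table(tbl)
  rows <- purrr::map(ft_sample_ids(tbl), ~ octave_histogram(tbl, .x))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("asv_octave", class(out))
  out
}

#' Write an octave summary as TSV
#'
#' @param octave An [octave_summary()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_octave <- function(octave, path) {
  df <- as.data.frame(octave)
  df$low_edge <- format(df$low_edge, scientific = FALSE, trim = TRUE)
  df$high_edge <- format(df$high_edge, scientific = FALSE, trim = TRUE)
  body <- if (nrow(df)) {
    m <- vapply(df, as.character, character(nrow(df)))
    if (nrow(df) == 1) m <- matrix(m, nrow = 1)
    apply(m, 1, paste, collapse = "\t")
  }
  lines <- c(paste(names(df), collapse = "\t"), body)
  write_lines_utf8(lines, path)
}
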