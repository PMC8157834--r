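#' Parameters for crosstalk removal
#'
#' Crosstalk (index hopping) moves a small fraction of a feature's reads into
#' the wrong samples during demultiplexing, creating spurious low-count
#' entries that inflate diversity estimates. The filter models the expected
#' per-sample leak of feature *i* as `e_i = gamma * C_i / N` (`C_i` the
#' feature's total count, `N` the number of samples) and scores each positive
#' entry `x_ij` with `s_ij = e_i / (e_i + x_ij)`; entries with `s_ij >= tau`
#' are treated as leaked and zeroed. With the default `tau = 1/3` this flags
#' exactly the entries with `x_ij <= 2 * e_i`, a "within twofold of the
#' expected leak" cut. `gamma = 0.01` matches the order of magnitude of
#' reported index-hopping rates on patterned flow cells.
#'
#' Two guards keep the filter conservative: features with total count below
#' `min_total` are skipped, and a feature is skipped (left untouched and
#' reported) when zeroing its flagged entries would remove more than
#' `max_row_loss` of its reads — that pattern looks like a genuinely rare,
#' evenly spread feature rather than leakage.
#'
#' @param gamma Expected leaked fraction of each feature's reads, in `[0, 1]`.
#' @param tau Score threshold in `(0, 1)`; entries with score `>= tau` are
#'   flagged. Ties are flagged (conservative toward removal).
#' @param max_row_loss Maximum fraction of a feature's reads that may be
#'   removed before the feature is skipped instead.
#' @param min_total Features with total count below this are skipped.
#' @return A list of validated parameters, class `crosstalk_params`.
#' @export
crosstalk_params <- function(gamma = 0.01, tau = 1 / 3, max_row_loss = 0.1,
                             min_total = 1L) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1) {
    stop_precondition("gamma must be a single number in [0, 1]")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    stop_precondition("tau must be a single number in (0, 1)")
  }
  if (!is.numeric(max_row_loss) || max_row_loss < 0 || max_row_loss > 1) {
    stop_precondition("max_row_loss must be in [0, 1]")
  }
  structure(list(gamma = gamma, tau = tau, max_row_loss = max_row_loss,
                 min_total = as.integer(min_total)),
            class = "crosstalk_params")
}

#' Expected per-sample leak profile of a feature table
#'
#' For every feature computes its total count `C_i` over all samples and the
#' expected per-sample leak `e_i = gamma * C_i / N` under a uniform-leak
#' model across the `N` samples.
#'
#' @param tbl Feature table tibble.
#' @param gamma Leaked fraction in `[0, 1]`.
#' @return Tibble with columns `feature_id`, `total`, `expected_leak`; the
#'   number of samples is attached as attribute `n_samples`.
#' @examples
#' tbl <- feature_table(matrix(c(994L, 2L, 2L, 2L), 1))
#' leak_profile(tbl, gamma = 0.01)$expected_leak # 2.5
#' @export
leak_profile <- function(tbl, gamma = 0.01) {
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) {
    stop_precondition("gamma must be in [0, 1]")
  }
  x <- ft_counts(tbl)
  n <- ncol(x)
  if (n < 1) stop_precondition("table has no samples")
  totals <- as.integer(rowSums(x))
  out <- tibble(feature_id = tbl$feature_id, total = totals,
                expected_leak = gamma * totals / n)
  attr(out, "n_samples") <- n
  attr(out, "gamma") <- gamma
  out
}

#' Crosstalk scores for every table entry
#'
#' Scores each entry `x_ij` with `s_ij = e_i / (e_i + x_ij)` for `x_ij > 0`
#' and 0 where `x_ij = 0`. Scores lie in `(0, 1]` and decrease strictly in
#' the count, so larger scores are more crosstalk-like.
#'
#' @param tbl Feature table tibble.
#' @param profile A [leak_profile()] computed from a table of the same shape;
#'   computed from `tbl` with `gamma` when omitted.
#' @param gamma Used only when `profile` is missing.
#' @return Tibble shaped like `tbl` with numeric score columns.
#' @export
crosstalk_scores <- function(tbl, profile = NULL, gamma = 0.01) {
  x <- ft_counts(tbl)
  if (is.null(profile)) profile <- leak_profile(tbl, gamma)
  if (!identical(profile$feature_id, tbl$feature_id) ||
      !identical(attr(profile, "n_samples"), ncol(x))) {
    stop_consistency("leak profile does not match the table's features/samples")
  }
  s <- score_matrix(x, profile$expected_leak)
  out <- tibble(feature_id = tbl$feature_id)
  for (j in seq_len(ncol(x))) out[[colnames(x)[j]]] <- s[, j]
  out
}

score_matrix <- function(x, e) {
  s <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  pos <- x > 0L
  em <- matrix(e, nrow(x), ncol(x))
  s[pos] <- em[pos] / (em[pos] + x[pos])
  s
}

#' Remove between-sample crosstalk from a feature table
#'
#' Zeroes every positive entry whose crosstalk score reaches the threshold,
#' leaving all other entries exactly as they were: counts are never
#' decremented, because the goal is removing spurious presence (diversity
#' inflation), not abundance correction. Features caught by the `min_total`
#' or `max_row_loss` guards pass through unchanged and are reported as
#' skipped; all-zero features pass through without being counted as skipped.
#'
#' @param tbl Feature table tibble.
#' @param params A [crosstalk_params()] object.
#' @param keep_scores Keep the full score matrix in the report (diagnostics).
#' @return An object of class `asv_crosstalk`: list with `table` (the
#'   filtered feature table), `report` (totals plus a per-feature tibble) and
#'   `params`. Use [tidy()] for per-feature outcomes and [glance()] for the
#'   one-row summary.
#' @examples
#' tbl <- feature_table(matrix(c(994L, 2L, 2L, 2L), 1,
#'                             dimnames = list("asv1", paste0("S", 1:4))))
#' remove_crosstalk(tbl)$table
#' @export
remove_crosstalk <- function(tbl, params = crosstalk_params(),
                             keep_scores = FALSE) {
  if (!inherits(params, "crosstalk_params")) {
    params <- do.call(crosstalk_params, as.list(params))
  }
  x <- ft_counts(tbl)
  if (ncol(x) < 1) stop_precondition("table has no samples")
  totals <- rowSums(x)
  e <- params$gamma * totals / ncol(x)
  s <- score_matrix(x, e)
  flagged <- x > 0L & s >= params$tau

  skip_reason <- rep(NA_character_, nrow(x))
  active <- totals > 0
  low <- active & totals < params$min_total
  skip_reason[low] <- "below_min_total"
  loss <- rowSums(x * (flagged & !low))
  lossy <- active & !low & loss > params$max_row_loss * totals
  skip_reason[lossy] <- "max_row_loss"

  zero <- flagged & !low & !lossy
  out <- x
  out[zero] <- 0L

  per_feature <- tibble(
    feature_id = tbl$feature_id,
    total = as.integer(totals),
    expected_leak = e,
    entries_zeroed = as.integer(rowSums(zero)),
    reads_removed = as.integer(rowSums(x * zero)),
    skipped = !is.na(skip_reason),
    skip_reason = skip_reason
  )
  report <- list(
    entries_zeroed = sum(per_feature$entries_zeroed),
    reads_removed = sum(per_feature$reads_removed),
    n_features_skipped = sum(per_feature$skipped),
    per_feature = per_feature,
    scores = if (keep_scores) s
  )
  structure(list(table = feature_table(out), report = report, params = params),
            class = "asv_crosstalk")
}

#' @export
print.asv_crosstalk <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<asv_crosstalk> zeroed %d entries (%d reads) across %d features; %d features skipped\n",
    r$entries_zeroed, r$reads_removed,
    sum(x$report$per_feature$entries_zeroed > 0), r$n_features_skipped))
  invisible(x)
}

#' @rdname remove_crosstalk
#' @param x An `asv_crosstalk` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.asv_crosstalk <- function(x, ...) x$report$per_feature

#' @rdname remove_crosstalk
#' @exportS3Method generics::glance
glance.asv_crosstalk <- function(x, ...) {
  tibble(entries_zeroed = x$report$entries_zeroed,
         reads_removed = x$report$reads_removed,
         n_features_skipped = x$report$n_features_skipped,
         gamma = x$params$gamma, tau = x$params$tau)
}
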