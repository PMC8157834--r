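#' Policy governing spacer splitting and overlap merging
#'
#' Denoising variable-length amplicons (e.g. fungal ITS) without joining the
#' paired reads yields representative sequences in which forward and reverse
#' fragments are concatenated with a run of `N`s. Fragments whose true
#' amplicon is short enough do overlap and can be merged after the fact;
#' genuinely long amplicons have a real gap and must stay concatenated.
#'
#' @param spacer_min_run Minimum run of `N` treated as a concatenation
#'   spacer. DADA2 emits 10 `N`s; tolerating runs of 5 or more is robust to
#'   upstream trimming, while isolated ambiguity `N`s (shorter runs) never
#'   split a sequence.
#' @param min_overlap Smallest overlap length considered real (bases).
#' @param max_mismatch_fraction Mismatches tolerated within an overlap of
#'   length `L`, as a fraction (at most `floor(f * L)` mismatches). Denoised
#'   sequences are consensus sequences, so the default demands exact
#'   overlaps.
#' @return A validated list of class `merge_policy`.
#' @export
merge_policy <- function(spacer_min_run = 5L, min_overlap = 12L,
                         max_mismatch_fraction = 0) {
  if (spacer_min_run < 1 || min_overlap < 1) {
    stop_precondition("spacer_min_run and min_overlap must be >= 1")
  }
  if (max_mismatch_fraction < 0 || max_mismatch_fraction > 1) {
    stop_precondition("max_mismatch_fraction must be in [0, 1]")
  }
  structure(list(spacer_min_run = as.integer(spacer_min_run),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_fraction = max_mismatch_fraction),
            class = "merge_policy")
}

#' Split an N-concatenated sequence into its two fragments
#'
#' A sequence splits when it contains exactly one maximal run of at least
#' `spacer_min_run` `N`s, strictly internal, with `N`-free flanks. Two or
#' more qualifying runs are ambiguous (warned, no split); shorter runs are
#' ambiguity calls, not spacers, and never split.
#'
#' @param seq Uppercase DNA string over `{A,C,G,T,N}`.
#' @param spacer_min_run Minimum qualifying run length.
#' @return A list with `left`, `right`, `spacer_len`, or `NULL` when the
#'   sequence is not splittable.
#' @examples
#' split_concatenated(paste0("ACGT", strrep("N", 10), "TTGG"))
#' @export
split_concatenated <- function(seq, spacer_min_run = 5L) {
  stopifnot(is.character(seq), length(seq) == 1)
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1L) return(NULL)
  len <- attr(m, "match.length")
  qual <- len >= spacer_min_run
  if (sum(qual) == 0) return(NULL)
  if (sum(qual) > 1) {
    warn(sprintf("sequence has %d candidate spacer runs; not splitting", sum(qual)))
    return(NULL)
  }
  start <- m[qual]
  spacer <- len[qual]
  end <- start + spacer - 1L
  if (start == 1L || end == nchar(seq)) return(NULL)
  left <- substr(seq, 1L, start - 1L)
  right <- substr(seq, end + 1L, nchar(seq))
  if (grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE)) {
    warn("flanking fragments contain N; not splitting")
    return(NULL)
  }
  list(left = left, right = right, spacer_len = as.integer(spacer))
}

#' Merge two fragments by suffix-prefix overlap
#'
#' Candidate overlap lengths `L` are scanned from `min(|left|, |right|)` down
#' to `min_overlap`; the overlap aligns the length-`L` suffix of `left` with
#' the length-`L` prefix of `right`. The largest `L` whose mismatch count is
#' within policy is accepted and the merge returns
#' `left + right[(L+1):]`, so mismatching positions inside the overlap keep
#' the left (forward-read-derived) base. The merged length obeys
#' `|merged| = |left| + |right| - L`.
#'
#' @param pair A list with `left` and `right` (e.g. from
#'   [split_concatenated()]), or the left fragment as a string.
#' @param right The right fragment when `pair` is a string.
#' @param policy A [merge_policy()].
#' @return The merged DNA string, or `NULL` when no acceptable overlap
#'   exists.
#' @export
overlap_merge <- function(pair, right = NULL, policy = merge_policy()) {
  if (is.list(pair)) {
    left <- pair$left
    right <- pair$right
  } else {
    left <- pair
  }
  nl <- nchar(left)
  nr <- nchar(right)
  if (min(nl, nr) < policy$min_overlap) return(NULL)
  lraw <- charToRaw(left)
  rraw <- charToRaw(right)
  for (L in seq(min(nl, nr), policy$min_overlap)) {
    mism <- sum(lraw[(nl - L + 1L):nl] != rraw[1:L])
    if (mism <= floor(policy$max_mismatch_fraction * L)) {
      return(paste0(left, substr(right, L + 1L, nr)))
    }
  }
  NULL
}

#' Resolve concatenated features in a dataset
#'
#' Applies [split_concatenated()] and [overlap_merge()] to every
#' representative sequence: features that merge get their merged sequence,
#' features with a real gap stay concatenated, features without a spacer
#' pass through. Features whose final sequences are identical are collapsed
#' into one feature whose per-sample counts are the elementwise sum, so
#' per-sample column totals are exactly conserved. The collapsed feature
#' keeps the id of the member with the largest total count (ties: first in
#' input order) and that member's taxonomy.
#'
#' @param ds An [asv_dataset()] with sequences.
#' @param policy A [merge_policy()].
#' @return An object of class `asv_merge`: list with `dataset` (the merged
#'   dataset) and `report`. [tidy()] gives per-feature outcomes, [glance()]
#'   the counts.
#' @export
merge_features <- function(ds, policy = merge_policy()) {
  stopifnot(inherits(ds, "asv_dataset"))
  if (is.null(ds$sequences)) {
    stop_precondition("dataset has no representative sequences to merge")
  }
  fids <- ds$table$feature_id
  seqs <- ds$sequences$sequence[match(fids, ds$sequences$feature_id)]

  outcome <- character(length(fids))
  final <- seqs
  for (i in seq_along(seqs)) {
    sp <- split_concatenated(seqs[i], policy$spacer_min_run)
    if (is.null(sp)) {
      outcome[i] <- "passthrough"
      next
    }
    mg <- overlap_merge(sp, policy = policy)
    if (is.null(mg)) {
      outcome[i] <- "kept_concatenated"
    } else {
      outcome[i] <- "merged"
      final[i] <- mg
    }
  }

  # Collapse features whose final sequences coincide, conserving counts.
  x <- ft_counts(ds$table)
  grp <- match(final, final)            # index of first occurrence
  totals <- rowSums(x)
  kept_of <- vapply(unique(grp), function(g) {
    members <- which(grp == g)
    members[which.max(totals[members])]
  }, integer(1))
  kept_of <- kept_of[order(kept_of)]
  new_x <- matrix(0L, length(kept_of), ncol(x),
                  dimnames = list(fids[kept_of], colnames(x)))
  kept_for <- integer(length(fids))
  for (k in seq_along(kept_of)) {
    members <- which(grp == grp[kept_of[k]])
    kept_for[members] <- kept_of[k]
    new_x[k, ] <- as.integer(colSums(x[members, , drop = FALSE]))
  }

  new_table <- feature_table(new_x)
  new_seqs <- tibble(feature_id = fids[kept_of], sequence = final[kept_of])
  new_tax <- if (!is.null(ds$taxonomy)) {
    ds$taxonomy[match(fids[kept_of], ds$taxonomy$feature_id), ]
  }
  out_ds <- asv_dataset(new_table, new_seqs, new_tax, ds$metadata)

  per_feature <- tibble(feature_id = fids, outcome = outcome,
                        kept_as = fids[kept_for])
  report <- list(
    n_merged = sum(outcome == "merged"),
    n_kept_concatenated = sum(outcome == "kept_concatenated"),
    n_passthrough = sum(outcome == "passthrough"),
    n_collapsed = length(fids) - length(kept_of),
    per_feature = per_feature
  )
  structure(list(dataset = out_ds, report = report, policy = policy),
            class = "asv_merge")
}

#' @export
print.asv_merge <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<asv_merge> merged %d, kept concatenated %d, passthrough %d; collapsed %d duplicate pair(s)\n",
    r$n_merged, r$n_kept_concatenated, r$n_passthrough, r$n_collapsed))
  invisible(x)
}

#' @rdname merge_features
#' @param x An `asv_merge` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.asv_merge <- function(x, ...) x$report$per_feature

#' @rdname merge_features
#' @exportS3Method generics::glance
glance.asv_merge <- function(x, ...) {
  tibble(n_merged = x$report$n_merged,
         n_kept_concatenated = x$report$n_kept_concatenated,
         n_passthrough = x$report$n_passthrough,
         n_collapsed = x$report$n_collapsed)
}
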