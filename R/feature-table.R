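#' Build a feature table tibble from a count matrix
#'
#' A feature table is the central object of every stage: a tibble whose first
#' column `feature_id` holds unique feature (ASV/OTU) identifiers and whose
#' remaining columns hold non-negative integer read counts, one column per
#' sample. All `asvpost` functions accept and return this shape so calls
#' chain with the pipe.
#'
#' @param counts Integer matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids Optional character vectors overriding the
#'   matrix dimnames.
#' @return A tibble with columns `feature_id` and one integer column per
#'   sample.
#' @examples
#' feature_table(matrix(1:4, 2, dimnames = list(c("a", "b"), c("S1", "S2"))))
#' @export
feature_table <- function(counts, feature_ids = rownames(counts),
                          sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(feature_ids)) feature_ids <- sprintf("ASV_%d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(counts)))
  tbl <- tibble(feature_id = as.character(feature_ids))
  for (j in seq_along(sample_ids)) tbl[[sample_ids[[j]]]] <- unname(counts[, j])
  validate_feature_table(tbl)
}

#' Validate feature-table invariants
#'
#' Checks that counts are non-negative integers, that feature and sample
#' identifiers are unique and non-empty, and that at least one sample column
#' is present (zero features are allowed).
#'
#' @param tbl A feature table tibble (`feature_id` + one column per sample).
#' @return The validated table, invisibly usable in a pipe.
#' @export
validate_feature_table <- function(tbl) {
  if (!is.data.frame(tbl) || ncol(tbl) < 1 || names(tbl)[1] != "feature_id") {
    stop_format("a feature table must be a data frame whose first column is `feature_id`")
  }
  sample_ids <- names(tbl)[-1]
  if (length(sample_ids) < 1) {
    stop_format("a feature table needs at least one sample column")
  }
  if (anyDuplicated(sample_ids) || any(sample_ids == "")) {
    stop_format("sample ids must be unique and non-empty")
  }
  fid <- tbl$feature_id
  if (anyDuplicated(fid) || any(fid == "") || anyNA(fid)) {
    stop_format("feature ids must be unique and non-empty")
  }
  for (s in sample_ids) {
    v <- tbl[[s]]
    if (is.double(v)) {
      if (any(v != trunc(v))) {
        bad <- fid[which(v != trunc(v))[1]]
        stop_format(sprintf("non-integer count at feature '%s', sample '%s'", bad, s))
      }
      v <- as.integer(v)
      tbl[[s]] <- v
    }
    if (!is.integer(v)) {
      stop_format(sprintf("sample column '%s' is not numeric", s))
    }
    if (anyNA(v) || any(v < 0L)) {
      bad <- fid[which(is.na(v) | v < 0L)[1]]
      stop_format(sprintf("missing or negative count at feature '%s', sample '%s'", bad, s))
    }
  }
  as_tibble(tbl)
}

# Feature table tibble -> integer matrix with dimnames (features x samples).
ft_counts <- function(tbl) {
  tbl <- validate_feature_table(tbl)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tbl$feature_id
  m
}

ft_sample_ids <- function(tbl) names(tbl)[-1]
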