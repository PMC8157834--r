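#' Simulate a microbial community feature table
#'
#' Generates a features-by-samples count table with the statistical
#' structure the post-denoising stages assume: per-feature total abundances
#' drawn from a log-normal distribution (the canonical model for microbial
#' community abundance profiles), each feature present only in a small
#' "home" subset of samples, and its reads spread over the home samples
#' uniformly at random. With the default of one home sample per feature the
#' community is sample-exclusive, the cleanest backdrop against which
#' injected crosstalk is visible.
#'
#' All randomness is driven by the explicit `seed` through an isolated RNG
#' scope, so the same arguments always reproduce the same table,
#' bit-for-bit, and the caller's RNG state is untouched.
#'
#' @param n_features,n_samples Table dimensions (both >= 1).
#' @param seed Integer seed; required.
#' @param meanlog,sdlog Parameters of the log-normal feature-total
#'   distribution (defaults: median ~400 reads, sd of log counts 1.5).
#' @param home_samples Number of samples each feature is allowed to occupy.
#' @return A feature table tibble.
#' @export
simulate_community <- function(n_features, n_samples, seed,
                               meanlog = 6, sdlog = 1.5, home_samples = 1L) {
  if (n_features < 1 || n_samples < 1) {
    stop_precondition("n_features and n_samples must be >= 1")
  }
  if (home_samples < 1 || home_samples > n_samples) {
    stop_precondition("home_samples must be in [1, n_samples]")
  }
  withr::with_seed(seed, {
    totals <- pmax(1, round(rlnorm(n_features, meanlog, sdlog)))
    x <- matrix(0L, n_features, n_samples,
                dimnames = list(sprintf("ASV_%04d", seq_len(n_features)),
                                sprintf("S%02d", seq_len(n_samples))))
    for (i in seq_len(n_features)) {
      home <- sample.int(n_samples, home_samples)
      x[i, home] <- as.integer(rmultinom(1, totals[i], rep(1, home_samples)))
    }
    feature_table(x)
  })
}

# Multivariate hypergeometric draw: remove `k` reads without replacement
# from pools of sizes `counts`.
rmvhyper <- function(counts, k) {
  out <- integer(length(counts))
  remaining <- k
  left <- sum(counts)
  for (j in seq_along(counts)) {
    if (remaining == 0L) break
    left <- left - counts[j]
    out[j] <- rhyper(1, counts[j], left, remaining)
    remaining <- remaining - out[j]
  }
  out
}

#' Inject crosstalk into a clean feature table
#'
#' Emulates demultiplexing misassignment: for each feature a
#' `Binomial(C_i, gamma)` number of reads is removed from its home samples
#' (proportionally, by sampling reads without replacement) and re-assigned
#' uniformly at random across all samples. Reads are moved, never created,
#' so per-feature row totals are conserved exactly. The ground-truth mask
#' records every entry that was zero before injection and positive after —
#' the spurious presences a crosstalk filter should remove.
#'
#' @param tbl Clean feature table tibble.
#' @param gamma Leak fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `asv_leak_truth`: list with `contaminated`
#'   and `clean` feature tables and `mask`, a tibble of injected entries
#'   (`feature_id`, `sample_id`, `count`).
#' @export
inject_crosstalk <- function(tbl, gamma, seed) {
  if (gamma < 0 || gamma >= 1) {
    stop_precondition("gamma must be in [0, 1)")
  }
  clean <- ft_counts(tbl)
  withr::with_seed(seed, {
    x <- clean
    n <- ncol(x)
    for (i in seq_len(nrow(x))) {
      total <- sum(x[i, ])
      if (total == 0L) next
      leaked <- rbinom(1, total, gamma)
      if (leaked == 0L) next
      removed <- rmvhyper(x[i, ], leaked)
      landed <- as.integer(rmultinom(1, leaked, rep(1, n)))
      x[i, ] <- x[i, ] - removed + landed
    }
    injected <- clean == 0L & x > 0L
    idx <- which(injected, arr.ind = TRUE)
    mask <- tibble(feature_id = rownames(x)[idx[, 1]],
                   sample_id = colnames(x)[idx[, 2]],
                   count = as.integer(x[injected]))
    structure(list(contaminated = feature_table(x),
                   clean = feature_table(clean),
                   mask = mask),
              class = "asv_leak_truth")
  })
}

#' @export
print.asv_leak_truth <- function(x, ...) {
  cat(sprintf("<asv_leak_truth> %d injected entries (%d reads)\n",
              nrow(x$mask), sum(x$mask$count)))
  invisible(x)
}

#' Simulate N-concatenated paired amplicon fragments
#'
#' Builds records that mimic denoised variable-length amplicons processed
#' without read joining: for each record a random DNA template is cut into a
#' forward and a reverse fragment of `read_len` bases whose true overlap is
#' drawn from `overlap_range` (negative values mean the amplicon is longer
#' than the two reads cover — a true gap), and the fragments are joined with
#' a run of `spacer_len` `N`s. The per-record template length is therefore
#' `2 * read_len - overlap` (plus the gap when the overlap is negative).
#' Records whose true overlap meets a merge policy's `min_overlap` are
#' exactly mergeable back to their template; records with a gap are not.
#'
#' @param n Number of records.
#' @param read_len Fragment length in bases.
#' @param overlap_range Integer `c(min, max)` for the true overlap; negative
#'   = gap.
#' @param spacer_len Length of the joining `N` run.
#' @param seed Integer seed.
#' @return A list with `records` (tibble `feature_id`, `sequence`) and
#'   `truth` (tibble `feature_id`, `template`, `true_overlap`).
#' @export
simulate_concatenated_pairs <- function(n, read_len = 120L,
                                        overlap_range = c(15L, 40L),
                                        spacer_len = 10L, seed) {
  if (n < 1 || read_len < 1 || spacer_len < 1) {
    stop_precondition("n, read_len and spacer_len must be >= 1")
  }
  if (length(overlap_range) != 2 || overlap_range[1] > overlap_range[2] ||
      overlap_range[2] >= read_len) {
    stop_precondition("overlap_range must be c(min, max) with max < read_len")
  }
  withr::with_seed(seed, {
    ids <- sprintf("PAIR_%04d", seq_len(n))
    overlaps <- sample(seq(overlap_range[1], overlap_range[2]), n, replace = TRUE)
    templates <- character(n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      o <- overlaps[i]
      tlen <- 2L * read_len - o
      template <- paste(sample(c("A", "C", "G", "T"), tlen, replace = TRUE),
                        collapse = "")
      left <- substr(template, 1L, read_len)
      right <- substr(template, tlen - read_len + 1L, tlen)
      templates[i] <- template
      seqs[i] <- paste0(left, strrep("N", spacer_len), right)
    }
    list(records = tibble(feature_id = ids, sequence = seqs),
         truth = tibble(feature_id = ids, template = templates,
                        true_overlap = as.integer(overlaps)))
  })
}
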