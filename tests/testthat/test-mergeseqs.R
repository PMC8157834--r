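test_that("spacer splitting handles the canonical and degenerate cases", {
  sp <- split_concatenated(paste0("ACGT", strrep("N", 10), "TTGG"))
  expect_equal(sp, list(left = "ACGT", right = "TTGG", spacer_len = 10L))
  # run shorter than the threshold is an ambiguity call, not a spacer
  expect_null(split_concatenated("ACGTNACGT"))
  # runs touching either end are not internal
  expect_null(split_concatenated(paste0(strrep("N", 6), "ACGT")))
  expect_null(split_concatenated(paste0("ACGT", strrep("N", 6))))
  # no N at all
  expect_null(split_concatenated("ACGTACGT"))
  # two qualifying runs are ambiguous: warn and refuse
  expect_warning(
    expect_null(split_concatenated(
      paste0("ACGT", strrep("N", 6), "CCGG", strrep("N", 6), "TTAA"))),
    "candidate spacer")
  # N inside a flank breaks the N-free fragment contract: refuse
  expect_warning(
    expect_null(split_concatenated(paste0("ACNGT", strrep("N", 6), "TTGG"))),
    "flanking")
})

test_that("overlap merging recovers a template cut into overlapping fragments", {
  withr::with_seed(61, {
    template <- paste(sample(c("A", "C", "G", "T"), 28, replace = TRUE),
                      collapse = "")
    left <- substr(template, 1, 20)
    right <- substr(template, 9, 28)   # exact 12-base junction
    merged <- overlap_merge(left, right)
    expect_equal(merged, template)
    expect_equal(nchar(merged), nchar(left) + nchar(right) - 12)
  })
})

test_that("identical fragments collapse to themselves and short overlaps fail", {
  x <- "ACGTACGTACGTACGT"
  expect_equal(overlap_merge(x, x), x)
  # exact overlap one base below the minimum is rejected
  left <- paste0(strrep("G", 20), strrep("A", 11))
  right <- paste0(strrep("A", 11), strrep("C", 20))
  expect_null(overlap_merge(left, right, policy = merge_policy(min_overlap = 12)))
  expect_equal(overlap_merge(left, right, policy = merge_policy(min_overlap = 11)),
               paste0(strrep("G", 20), strrep("A", 11), strrep("C", 20)))
})

test_that("mismatches within tolerance merge and keep the left base", {
  left <- "CCCCCCCCGGGGAAAAAAAATT"
  right <- sub("^GGGGAAAAAAAATT", "GGGGAAAAAAAACT", "GGGGAAAAAAAATTAAAA")
  # overlap of 14 with one mismatch (T vs C at a junction position)
  expect_null(overlap_merge(left, right, policy = merge_policy(min_overlap = 14)))
  merged <- overlap_merge(left, right,
                          policy = merge_policy(min_overlap = 14,
                                                max_mismatch_fraction = 0.1))
  expect_equal(merged, paste0(left, "AAAA"))
})

test_that("the merged length law holds over random overlapping pairs", {
  withr::with_seed(71, {
    for (rep in 1:25) {
      o <- sample(12:30, 1)
      tlen <- 80L
      template <- paste(sample(c("A", "C", "G", "T"), tlen, replace = TRUE),
                        collapse = "")
      left <- substr(template, 1, (tlen + o) / 2)
      right <- substr(template, nchar(left) - o + 1, tlen)
      merged <- overlap_merge(left, right)
      expect_false(is.null(merged))
      expect_true(nchar(merged) <= nchar(left) + nchar(right) - 12)
    }
  })
})

test_that("features merging to the same sequence collapse with count conservation", {
  template <- paste0(strrep("ACGT", 10), strrep("TGCA", 10))
  left <- substr(template, 1, 48)
  right <- substr(template, 33, 80)     # overlap 16
  concat <- paste0(left, strrep("N", 10), right)
  tbl <- feature_table(matrix(c(5L, 3L, 0L, 2L), 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("S1", "S2"))))
  seqs <- tibble::tibble(feature_id = c("a", "b"),
                         sequence = c(concat, template))
  tax <- tibble::tibble(feature_id = c("a", "b"),
                        Kingdom = c("Fungi", "Fungi"),
                        Genus = c("Aspergillus", "Penicillium"))
  ds <- asv_dataset(tbl, seqs, tax)
  res <- merge_features(ds)
  out <- res$dataset
  expect_equal(nrow(out$table), 1)
  # kept id is the member with the larger total (a: 8, b: 2)
  expect_equal(out$table$feature_id, "a")
  expect_equal(unname(unlist(out$table[1, -1])), c(5L, 5L))
  expect_equal(out$sequences$sequence, template)
  expect_equal(out$taxonomy$Genus, "Aspergillus")
  expect_equal(res$report$n_collapsed, 1)
  # column sums conserved
  expect_equal(colSums(as.matrix(out$table[, -1])),
               colSums(as.matrix(tbl[, -1])))
})

test_that("collapse ties go to the first feature in input order", {
  x <- strrep("ACGT", 8)
  tbl <- feature_table(matrix(c(4L, 4L), 2, 1,
                              dimnames = list(c("first", "second"), "S1")))
  seqs <- tibble::tibble(feature_id = c("first", "second"), sequence = c(x, x))
  res <- merge_features(asv_dataset(tbl, seqs))
  expect_equal(res$dataset$table$feature_id, "first")
  expect_equal(res$dataset$table$S1, 8L)
})

test_that("features without a spacer pass through and reports balance", {
  ds <- tiny_dataset()
  res <- merge_features(ds)
  expect_equal(res$report$n_passthrough, 3)
  expect_equal(res$report$n_merged + res$report$n_kept_concatenated +
                 res$report$n_passthrough, nrow(ds$table))
  expect_equal(res$dataset$table, ds$table)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_passthrough, 3)
})

test_that("merge_features is idempotent and needs sequences", {
  pp <- simulate_concatenated_pairs(20, seed = 81)
  tbl <- feature_table(matrix(sample(1:50, 20), 20, 1,
                              dimnames = list(pp$records$feature_id, "S1")))
  ds <- asv_dataset(tbl, pp$records)
  once <- merge_features(ds)$dataset
  twice <- merge_features(once)$dataset
  expect_equal(twice$table, once$table)
  expect_equal(twice$sequences, once$sequences)

  expect_error(merge_features(asv_dataset(tbl)),
               class = "asvpost_precondition_error")
})
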