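test_that("leak profile follows the closed form e_i = gamma * C_i / N", {
  tbl <- feature_table(matrix(c(100L, 200L, 300L, 400L, 0L, 0L, 0L, 0L,
                                rep(0L, 32)), 4))
  tbl10 <- feature_table(matrix(c(1000L, rep(0L, 9)), 1))
  expect_equal(leak_profile(tbl10, gamma = 0.01)$expected_leak, 1.0)
  expect_equal(leak_profile(tbl, gamma = 0)$expected_leak, rep(0, 4))
  tbl1 <- feature_table(matrix(c(40L, 7L), 2, 1))
  expect_equal(leak_profile(tbl1, gamma = 0.05)$expected_leak,
               0.05 * c(40, 7))
})

test_that("crosstalk scores hit the symmetry point and zero cases", {
  # x = e: score is exactly 1/2
  tbl <- feature_table(matrix(c(10L, 10L, 10L, 10L), 1))
  prof <- leak_profile(tbl, gamma = 1)  # e = 40/4 = 10 = x
  s <- crosstalk_scores(tbl, prof)
  expect_equal(unlist(s[1, -1], use.names = FALSE), rep(0.5, 4))
  # e = 0: scores vanish even for positive counts
  s0 <- crosstalk_scores(tbl, gamma = 0)
  expect_equal(unlist(s0[1, -1], use.names = FALSE), rep(0, 4))
  # direct evaluation: x = 2, e = 2.5 -> 2.5 / 4.5
  tbl2 <- feature_table(matrix(c(998L, 2L), 1))
  prof2 <- leak_profile(tbl2, gamma = 0.005)  # e = 0.005 * 1000 / 2 = 2.5
  s2 <- crosstalk_scores(tbl2, prof2)
  expect_equal(s2[[3]], 2.5 / 4.5, tolerance = 1e-12)
  # strictly decreasing in the count for fixed e > 0
  tbl3 <- feature_table(matrix(c(1L, 5L, 50L, 500L), 1))
  s3 <- unlist(crosstalk_scores(tbl3, gamma = 0.5)[1, -1], use.names = FALSE)
  expect_true(all(diff(s3) < 0))
})

test_that("a dominated row loses its leaked entries, reads accounted", {
  tbl <- feature_table(matrix(c(994L, 2L, 2L, 2L), 1,
                              dimnames = list("asv1", paste0("S", 1:4))))
  res <- remove_crosstalk(tbl)
  expect_equal(unname(unlist(res$table[1, -1])), c(994L, 0L, 0L, 0L))
  expect_equal(res$report$reads_removed, 6L)
  expect_equal(res$report$entries_zeroed, 3L)
  expect_equal(sum(as.matrix(tbl[, -1])) - sum(as.matrix(res$table[, -1])),
               res$report$reads_removed)
})

test_that("gamma = 0 is the identity and zero rows are not skipped", {
  tbl <- random_table(8, 5, seed = 21)
  res <- remove_crosstalk(tbl, crosstalk_params(gamma = 0))
  expect_equal(res$table, tbl)
  expect_equal(res$report$entries_zeroed, 0L)

  zero_row <- feature_table(matrix(0L, 2, 3))
  rz <- remove_crosstalk(zero_row)
  expect_equal(rz$table, zero_row)
  expect_equal(rz$report$n_features_skipped, 0L)
})

test_that("skip guards protect low-total and evenly spread features", {
  # min_total: feature below the floor passes through untouched
  tbl <- feature_table(matrix(c(3L, 1L, 0L, 0L), 1))
  res <- remove_crosstalk(tbl, crosstalk_params(gamma = 0.9, min_total = 10L))
  expect_equal(res$table, tbl)
  expect_equal(tidy(res)$skip_reason, "below_min_total")

  # max_row_loss: zeroing 6/16 reads exceeds the 10% cap, so skip
  even <- feature_table(matrix(c(10L, rep(1L, 6)), 1))
  rese <- remove_crosstalk(even, crosstalk_params(gamma = 0.5))
  expect_equal(rese$table, even)
  expect_equal(tidy(rese)$skip_reason, "max_row_loss")
  # ... but the same shape is filtered when the cap allows it
  resf <- remove_crosstalk(even, crosstalk_params(gamma = 0.5, max_row_loss = 0.5))
  expect_equal(unname(unlist(resf$table[1, -1])), c(10L, rep(0L, 6)))
})

test_that("filtering matches the brute-force oracle on random tables", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      tbl <- random_table(sample(1:10, 1), sample(1:10, 1))
      gamma <- sample(c(0.005, 0.01, 0.05, 0.2), 1)
      res <- remove_crosstalk(tbl, crosstalk_params(gamma = gamma))
      expect_equal(res$table, oracle_remove_crosstalk(tbl, gamma = gamma))
    }
  })
})

test_that("filtering obeys ordering, monotonicity and scale covariance", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      tbl <- random_table(sample(1:8, 1), sample(2:8, 1))
      res <- remove_crosstalk(tbl, crosstalk_params(gamma = 0.05))
      x <- as.matrix(tbl[, -1])
      y <- as.matrix(res$table[, -1])
      # elementwise output <= input, integrality preserved
      expect_true(all(y <= x))
      expect_true(is.integer(y))
      # within-row monotonicity: zeroing a count zeroes all smaller ones
      for (i in seq_len(nrow(x))) {
        zeroed <- x[i, ] > 0 & y[i, ] == 0
        kept <- x[i, ] > 0 & y[i, ] > 0
        if (any(zeroed) && any(kept)) {
          expect_true(max(x[i, zeroed]) <= min(x[i, kept]))
        }
      }
      # scale covariance: doubling a row leaves its zeroed pattern unchanged
      k <- sample(2:5, 1)
      scaled <- tbl
      for (j in seq_along(scaled)[-1]) scaled[[j]] <- scaled[[j]] * k
      res2 <- remove_crosstalk(scaled, crosstalk_params(gamma = 0.05))
      expect_equal(as.matrix(res2$table[, -1]) == 0, y == 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("tidy and glance summarize the filtering result consistently", {
  tbl <- random_table(6, 4, seed = 51)
  res <- remove_crosstalk(tbl, crosstalk_params(gamma = 0.1))
  td <- tidy(res)
  gl <- glance(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$reads_removed), gl$reads_removed)
  expect_equal(sum(td$entries_zeroed), gl$entries_zeroed)
})

test_that("invalid parameters are rejected up front", {
  expect_error(crosstalk_params(gamma = 1.5), class = "asvpost_precondition_error")
  expect_error(crosstalk_params(tau = 0), class = "asvpost_precondition_error")
  expect_error(crosstalk_params(max_row_loss = -0.1),
               class = "asvpost_precondition_error")
})
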