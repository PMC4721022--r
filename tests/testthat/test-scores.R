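test_that("entropy sees ratios only; complexity also sees frequencies", {
  expect_equal(entropy_bits(c(3, 7)), 0.8813, tolerance = 1e-4)
  expect_identical(entropy_bits(c(3, 7)), entropy_bits(c(30, 70)))
  expect_equal(entropy_bits(c(5, 0)), 0)
  expect_error(entropy_bits(c(0, 0)), "positive count")
  expect_error(entropy_bits(c(-1, 2)), "non-negative")
  # complexity scales with counts where entropy cannot
  c1 <- complexity(rbind(c(3, 7), c(7, 3)))$C
  c10 <- complexity(rbind(c(30, 70), c(70, 30)))$C
  expect_gt(c10, c1)
})

test_that("complexity and maximum complexity match hand-derived tables", {
  pure <- rbind(c(4, 0), c(0, 4))
  expect_equal(complexity(pure), list(C_row = 0, C_column = 0, C = 0))
  flat <- rbind(c(2, 2), c(2, 2))
  expect_equal(complexity(flat), list(C_row = 8, C_column = 8, C = 16))
  onesided <- rbind(c(0, 4), c(0, 4))
  expect_equal(complexity(onesided)$C_row, 0)
  expect_equal(complexity(onesided)$C_column, 8)
  expect_equal(max_complexity(flat)$C_max, 16)
  m <- max_complexity(rbind(c(2, 1), c(4, 3)))  # n = 10, f+ = 3, f- = 7
  expect_equal(m$C_row_max, 10)
  expect_equal(m$C_column_max, 8.8129, tolerance = 1e-4)
  # empty class row: column part vanishes
  expect_equal(max_complexity(rbind(c(3, 5), c(0, 0)))$C_max, 8)
})

test_that("relative simplicity spans [0, 1] with the documented anchors", {
  expect_equal(relative_simplicity(rbind(c(4, 0), c(0, 4))), 1)
  expect_equal(relative_simplicity(rbind(c(0, 4), c(4, 0))), 1)
  expect_equal(relative_simplicity(rbind(c(2, 2), c(2, 2))), 0)
  # scale sensitivity: the anchors survive scaling even though C and C_max
  # individually change
  expect_equal(relative_simplicity(rbind(c(40, 0), c(0, 40))), 1)
  expect_equal(relative_simplicity(rbind(c(20, 20), c(20, 20))), 0)
  expect_false(complexity(rbind(c(12, 4), c(4, 12)))$C ==
               complexity(rbind(c(3, 1), c(1, 3)))$C)
})

test_that("RS stays in [0, 1] and is permutation invariant on random tables", {
  set.seed(77)
  for (rep in 1:300) {
    tab <- random_table(r = sample(c(2, 4), 1), halves = rep %% 2 == 0)
    rs <- relative_simplicity(tab)
    expect_gte(rs, 0); expect_lte(rs, 1)
    expect_equal(relative_simplicity(tab[, sample(ncol(tab))]), rs,
                 tolerance = 1e-12)  # addition order changes under permutation
    expect_identical(relative_simplicity(tab[c(2, 1), ]), rs)
    expect_equal(rs, rs_oracle(tab))
  }
})

test_that("RS grows as mass moves from balanced to class-pure columns", {
  # enumerate 2x2 tables with fixed margins f+ = f- = 6, f1 = f2 = 6 and
  # increasing diagonal concentration: RS must increase strictly
  rs_seq <- vapply(3:6, function(a)
    relative_simplicity(rbind(c(a, 6 - a), c(6 - a, a))), numeric(1))
  expect_true(all(diff(rs_seq) > 0))
  expect_equal(rs_seq[1], 0)
  expect_equal(rs_seq[4], 1)
})

test_that("corrected 2x2 chi-square reproduces all printed example values", {
  expect_equal(chi2_2x2_corrected(rbind(c(4, 0), c(0, 4)))$statistic, 4.5)
  expect_equal(chi2_2x2_corrected(rbind(c(2, 2), c(2, 2)))$statistic, 0.5)
  expect_equal(chi2_2x2_corrected(rbind(c(0, 4), c(0, 4)))$statistic, 0)
  # the un-floored correction is essential: |ad-bc| - n/2 < 0 here
  lung1 <- rbind(c(41, 3), c(19, 1))
  expect_equal(chi2_2x2_corrected(lung1)$p_value, 0.7806, tolerance = 5e-4)
  expect_equal(chi2_2x2_corrected(lung1, "yates")$statistic, 0)
  gcm <- rbind(c(2, 9), c(10, 1))
  expect_equal(round(chi2_2x2_corrected(gcm)$p_value, 4), 0.0027)
  # the uncorrected variant agrees with the standard Pearson implementation
  set.seed(3)
  tab <- random_table(r = 2, max_count = 20)
  expect_equal(chi2_2x2_corrected(tab, "none")$statistic,
               unname(suppressWarnings(
                 chisq.test(tab, correct = FALSE)$statistic)))
})

test_that("2xr Pearson chi-square matches examples and the stats oracle", {
  expect_equal(chi2_2xr_pearson(rbind(c(2, 0, 0, 2), c(0, 2, 2, 0)))$statistic,
               8)
  p1 <- chi2_2xr_pearson(rbind(c(3, 1, 1, 6), c(0, 0, 0, 11)))
  expect_equal(p1$p_value, 0.0908, tolerance = 5e-4)
  expect_equal(p1$df, 3L)
  # margin-proportional table scores 0
  expect_equal(chi2_2xr_pearson(rbind(c(2, 4, 6), c(1, 2, 3)))$statistic, 0)
  set.seed(4)
  tab <- random_table(r = 4, max_count = 15)
  expect_equal(chi2_2xr_pearson(tab)$statistic,
               unname(suppressWarnings(
                 chisq.test(tab, correct = FALSE)$statistic)))
})

test_that("score backends dispatch to the right statistic", {
  pure <- rbind(c(4, 0), c(0, 4))
  flat <- rbind(c(2, 2), c(2, 2))
  expect_equal(score_backend("rs")(pure), 1)
  expect_equal(score_backend("chi2")(pure), 4.5)
  expect_equal(score_backend("chi2")(rbind(c(2, 0, 0, 2), c(0, 2, 2, 0))), 8)
  expect_equal(score_backend("entropy")(flat), 0)
  expect_equal(score_backend("entropy")(pure), 1)
  expect_error(score_backend("bogus"))
})
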