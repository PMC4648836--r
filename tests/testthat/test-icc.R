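test_that("identical columns give perfect agreement", {
  x <- cbind(c(5, 7, 9, 11), c(5, 7, 9, 11))
  expect_equal(icc_2_1(x)$icc, 1)
})

test_that("the worked 4x2 table matches the definitional ANOVA oracle", {
  x <- matrix(c(5, 6, 7, 8, 9, 10, 11, 12), ncol = 2, byrow = TRUE)
  res <- icc_2_1(x)
  expect_lt(abs(res$icc - icc_oracle(x)), 1e-10)
  expect_equal(res$icc, 0.930, tolerance = 1e-3)
})

test_that("random tables match the definitional oracle to 1e-10", {
  for (seed in 1:100) {
    x <- tunnelmetry:::with_local_seed(seed,
                                       matrix(rnorm(60, 7, 1.5), 20, 3))
    res <- icc_2_1(x)
    expect_lt(abs(res$icc - icc_oracle(x)), 1e-10)
    expect_lte(res$ci_low, res$icc + 1e-12)
    expect_gte(res$ci_high, res$icc - 1e-12)
  }
})

test_that("point estimate and CI match an independent reference implementation", {
  # Shrout & Fleiss 6 x 4 ratings; reference values computed with an
  # independent absolute-agreement ICC implementation
  sf <- matrix(c(9, 2, 5, 8,
                 6, 1, 3, 2,
                 8, 4, 6, 8,
                 7, 1, 2, 6,
                 10, 5, 6, 9,
                 6, 2, 4, 7), ncol = 4, byrow = TRUE)
  res <- icc_2_1(sf)
  expect_equal(res$icc, 0.289763779528, tolerance = 1e-9)
  expect_equal(round(res$ci_low, 2), 0.02)
  expect_equal(round(res$ci_high, 2), 0.76)

  tab <- matrix(c(8.543285, 9.46288, 8.720079,
                  5.540231, 4.9108, 7.100795,
                  8.292026, 7.76378, 9.715428,
                  8.126265, 7.959639, 5.903016,
                  5.338424, 9.226608, 7.073369), ncol = 3, byrow = TRUE)
  expect_equal(icc_2_1(tab)$icc, 0.362761012907, tolerance = 1e-9)
})

test_that("the qualitative bands match the reported classification", {
  expect_equal(classify_icc(0.899), "excellent")
  expect_equal(classify_icc(0.745), "fair_to_good")
  expect_equal(classify_icc(-0.004), "poor")
  # boundaries: 0.75 and 0.40 both belong to fair_to_good
  expect_equal(classify_icc(0.75), "fair_to_good")
  expect_equal(classify_icc(0.40), "fair_to_good")
  expect_equal(classify_icc(0.7500001), "excellent")
  expect_equal(classify_icc(0.3999999), "poor")
})

test_that("ICC is invariant to subject order and global shifts", {
  x <- tunnelmetry:::with_local_seed(11, matrix(rnorm(45, 6, 1), 15, 3))
  base <- icc_2_1(x)$icc
  perm <- tunnelmetry:::with_local_seed(12, sample(15))
  expect_equal(icc_2_1(x[perm, ])$icc, base, tolerance = 1e-12)
  expect_equal(icc_2_1(x + 3.7)$icc, base, tolerance = 1e-10)
})

test_that("a constant bias on one rater lowers absolute agreement", {
  # raters share a real subject effect, so baseline agreement is high
  x <- tunnelmetry:::with_local_seed(13, {
    subj <- rnorm(15, 6, 1.5)
    cbind(subj + rnorm(15, 0, 0.3), subj + rnorm(15, 0, 0.3),
          subj + rnorm(15, 0, 0.3))
  })
  base <- icc_2_1(x)$icc
  biased <- x
  biased[, 2] <- biased[, 2] + 1.5
  expect_gt(base, 0.8)
  expect_lt(icc_2_1(biased)$icc, base)
})

test_that("CI width shrinks with more subjects", {
  widths <- vapply(c(10, 80), function(n) {
    w <- vapply(1:20, function(s) {
      x <- tunnelmetry:::with_local_seed(1000 + 17 * n + s, {
        subj <- rnorm(n, 7, 1.5)
        cbind(subj + rnorm(n, 0, 0.5), subj + rnorm(n, 0, 0.5))
      })
      r <- icc_2_1(x)
      r$ci_high - r$ci_low
    }, numeric(1))
    median(w)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("degenerate and invalid tables are handled explicitly", {
  flat <- matrix(5, 4, 3)
  expect_warning(res <- icc_2_1(flat), "zero total variance")
  expect_equal(res$icc, 1)
  expect_equal(c(res$ci_low, res$ci_high), c(1, 1))
  expect_error(icc_2_1(matrix(1:4, 2, 2)), "at least 3")
  expect_error(icc_2_1(matrix(1:6, 3, 2) * NA), "complete")
})

test_that("difference summaries follow the definitional formulas", {
  expect_equal(difference_summary(c(5, 6, 7), c(5, 6, 7))$mean_diff_mm, 0)
  expect_equal(difference_summary(c(5, 6, 7), c(5, 6, 7))$sd_diff_mm, 0)
  r <- difference_summary(c(5.3, 6.3), c(5.0, 6.0))
  expect_equal(r$mean_diff_mm, 0.3)
  expect_equal(r$sd_diff_mm, 0)
  r2 <- difference_summary(c(5.2, 6.9), c(5.0, 7.0))
  expect_equal(r2$mean_diff_mm, 0.05)
  expect_equal(r2$sd_diff_mm, sd(c(0.2, -0.1)))
  expect_error(difference_summary(1:3, 1:4), "same length")
})

test_that("agreement reports summarise each method against the drill size", {
  ids <- sprintf("t%02d", 1:6)
  truths <- data.frame(id = ids, true_diameter_mm = c(5, 6, 7, 8, 8.5, 9))
  perfect <- do.call(rbind, lapply(c("cylinder_fit", "ct2d"), function(m) {
    data.frame(id = ids, method = m, diameter_mm = truths$true_diameter_mm)
  }))
  rep1 <- agreement_report(perfect, truths)
  expect_equal(nrow(rep1$agreement), 2)
  expect_true(all(rep1$agreement$icc == 1))
  expect_true(all(rep1$agreement$mean_diff_mm == 0))

  # intra-rater table appears when repeats are supplied
  rep2 <- agreement_report(perfect, truths, repeat_measurements = perfect)
  expect_equal(nrow(rep2$intra_rater), 2)
  expect_true(all(rep2$intra_rater$icc == 1))
})
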