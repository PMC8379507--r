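# frozen oracle values for the 6x2 rating fixtures were computed with an
# independent ANOVA mean-squares implementation of the agreement ICC
icc_fixture_1 <- cbind(c(34, 98, 121.5, 12, 55, 140),
                       c(36, 91, 130, 10, 61, 132))
icc_fixture_2 <- cbind(c(34, 98, 121.5, 12, 55, 140),
                       c(48, 75, 135, 28, 70, 121))

test_that("ICC(A,1) matches the closed-form fixtures and their CIs", {
  r1 <- icc_a1(icc_fixture_1)
  expect_equal(r1$estimate, 0.9924683085808719, tolerance = 1e-10)
  expect_equal(r1$ci_low, 0.9471744709152811, tolerance = 1e-8)
  expect_equal(r1$ci_high, 0.9989432915318555, tolerance = 1e-8)

  r2 <- icc_a1(icc_fixture_2)
  expect_equal(r2$estimate, 0.9314316737256993, tolerance = 1e-10)
  expect_equal(r2$ci_low, 0.5996781390337571, tolerance = 1e-8)
  expect_equal(r2$ci_high, 0.9901007444944396, tolerance = 1e-8)
})

test_that("ICC(A,1) rewards agreement and penalises offsets", {
  x <- c(10, 20, 30, 40, 50, 60)
  expect_equal(icc_a1(cbind(x, x))$estimate, 1.0)
  shifted <- icc_a1(cbind(x, x + 40))
  expect_lt(shifted$estimate, 0.7)  # absolute agreement penalises the offset
  expect_lte(shifted$estimate, 1)
  expect_lte(shifted$ci_low, shifted$estimate)
  expect_gte(shifted$ci_high, shifted$estimate)

  # estimate approaches 1 as rater noise vanishes
  withr::with_seed(401, {
    subj <- runif(12, 0, 100)
    ests <- vapply(c(10, 1, 0.01), function(sd)
      icc_a1(cbind(subj + rnorm(12, 0, sd), subj + rnorm(12, 0, sd)))$estimate,
      numeric(1))
    expect_true(all(diff(ests) > 0))
    expect_gt(ests[3], 0.999)
  })
  expect_error(icc_a1(cbind(c(1, NA), c(2, 3))), "complete")
  expect_error(icc_a1(matrix(1:2, ncol = 1)), "at least 2")
})

test_that("the KS gate accepts normal and rejects discrete or constant data", {
  withr::with_seed(402, {
    expect_true(ks_normality(rnorm(200)))
    expect_false(ks_normality(sample(0:1, 200, replace = TRUE)))
  })
  expect_false(ks_normality(rep(3, 20)))
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
  # uncorrected variant is available and agrees on a clear null case
  withr::with_seed(403, expect_true(ks_normality(rnorm(200), lilliefors = FALSE)))
})

test_that("normal samples take the t path with pooled-SD Cohen's d", {
  withr::with_seed(404, {
    a <- rnorm(30, 10, 2)
    b <- rnorm(28, 8, 2)
  })
  cmp <- compare_groups(a, b)
  expect_identical(cmp$test, "T_TEST")
  sp <- sqrt(((29) * var(a) + (27) * var(b)) / 56)
  expect_equal(unname(cmp$effect["d"]), (mean(a) - mean(b)) / sp)
  expect_equal(cmp$mean_diff, mean(a) - mean(b))
  # p equals the closed-form t CDF
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(1 / 30 + 1 / 28))
  expect_equal(cmp$p_value, 2 * pt(-abs(tstat), df = 56))
  expect_equal(cmp$statistic, tstat)

  same <- compare_groups(a, a)
  expect_equal(same$mean_diff, 0)
  expect_equal(unname(same$effect["d"]), 0)
})

test_that("non-normal samples fall back to Mann-Whitney with rank-biserial r", {
  withr::with_seed(405, {
    a <- rexp(40, 1 / 10)^2
    b <- rexp(40, 1 / 5)^2
  })
  cmp <- compare_groups(a, b)
  expect_identical(cmp$test, "MANN_WHITNEY")
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_true(abs(cmp$effect["rank_biserial"]) <= 1)

  sep <- compare_groups(c(1, 2, 3), c(4, 5, 6))  # complete separation
  expect_identical(sep$test, "MANN_WHITNEY")
  expect_equal(sep$statistic, 0)
  expect_equal(abs(unname(sep$effect["rank_biserial"])), 1)
  expect_equal(unname(sep$effect["rank_biserial"]), -1)  # a below b

  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("rank-biserial agrees with the pairwise-dominance oracle", {
  expect_equal(rank_biserial(6, 3, 4), 0)
  expect_equal(rank_biserial(1, 2, 2), 0.5)
  expect_equal(rank_biserial(0, 3, 3), 1)
  expect_error(rank_biserial(10, 3, 3), "lie in")

  withr::with_seed(406, {
    for (rep in 1:50) {
      na <- sample(2:5, 1); nb <- sample(2:5, 1)
      a <- sample(1:6, na, replace = TRUE)
      b <- sample(1:6, nb, replace = TRUE)
      dom <- (sum(outer(a, b, ">")) - sum(outer(a, b, "<"))) / (na * nb)
      u_b <- sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
      expect_equal(rank_biserial(u_b, na, nb), dom)
    }
  })
})

test_that("Fisher exact matches published 2x2 p-values and is symmetric", {
  expect_equal(fisher_exact(matrix(c(8, 24, 10, 21), 2, byrow = TRUE)), 0.585,
               tolerance = 0.001)
  expect_equal(fisher_exact(matrix(c(21, 11, 20, 11), 2, byrow = TRUE)), 1,
               tolerance = 1e-6)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1.0)
  withr::with_seed(407, {
    for (i in 1:20) {
      m <- matrix(sample(0:12, 4, replace = TRUE), 2)
      swapped <- m[2:1, 2:1]
      expect_equal(fisher_exact(m), fisher_exact(swapped))
    }
  })
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("raw TLX is the unweighted mean of the six subscales", {
  expect_equal(tlx_raw(rep(7.5, 6)), 7.5)
  expect_equal(round(tlx_raw(c(13, 3.5, 10, 7, 12, 8)), 2), 8.92)
  expect_equal(tlx_raw(rep(0, 6)), 0)
  expect_error(tlx_raw(1:5), "six")
})

test_that("the sample-size helper reproduces the normal-approximation table", {
  expect_identical(sample_size_two_group(0.8, 0.05, 0.9), 33L)
  expect_identical(sample_size_two_group(0.8, 0.05, 0.8), 25L)
  expect_identical(sample_size_two_group(1000, 0.05, 0.8), 1L)
  expect_error(sample_size_two_group(0), "positive")
  expect_error(sample_size_two_group(0.8, 1.5, 0.8), "lie in")
})
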