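test_that("identical condition columns give F = 0, p = 1", {
  m <- matrix(rnorm(5), 5, 3)
  res <- rm_anova(m, correct = "none")
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
})

test_that("a constant condition offset with no interaction noise is flagged", {
  base <- c(1, 2, 3)
  m <- cbind(base, base + 1)
  res <- rm_anova(m, correct = "none")
  expect_true(res$degenerate)
  expect_equal(res$f, Inf)
  expect_equal(res$p, 0)
})

test_that("RM-ANOVA F and p equal the stats::aov decomposition", {
  set.seed(20)
  for (i in 1:4) {
    m <- matrix(rnorm(5 * 3), 5, 3)
    res <- rm_anova(m, correct = "none")
    oracle <- aov_rm_oracle(m)
    expect_equal(res$f, oracle$f, tolerance = 1e-10)
    expect_equal(res$p, oracle$p, tolerance = 1e-10)
    expect_equal(res$df, c(2, 8))
  }
})

test_that("a replicate dimension can be averaged or stacked", {
  set.seed(21)
  arr <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  res_mean <- rm_anova(arr, correct = "none", replicates = "means")
  direct <- rm_anova(apply(arr, c(1, 2), mean), correct = "none")
  expect_equal(res_mean$f, direct$f)
  res_stack <- rm_anova(arr, correct = "none", replicates = "stack")
  expect_equal(res_stack$df, c(2, 2 * 7)) # 8 blocks
})

test_that("Mauchly's test is the two-level identity at k = 2", {
  m <- matrix(rnorm(10 * 2), 10, 2)
  res <- mauchly_test(m)
  expect_equal(res$w, 1)
  expect_equal(res$p, 1)
})

test_that("Mauchly W and p match the stats::mauchly.test oracle", {
  set.seed(22)
  for (i in 1:4) {
    m <- matrix(rnorm(12 * 4), 12, 4)
    if (i %% 2 == 0) m[, 1] <- m[, 1] * 3 # heteroscedastic cases
    res <- mauchly_test(m)
    fit <- stats::lm(m ~ 1)
    oracle <- stats::mauchly.test(fit, X = ~1)
    expect_equal(res$w, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$p, oracle$p.value, tolerance = 5e-3)
  }
})

test_that("Mauchly calibration: near-nominal rejection under sphericity", {
  set.seed(23)
  rej <- mean(vapply(1:400, function(i) {
    mauchly_test(matrix(rnorm(12 * 3), 12, 3))$p < 0.05
  }, logical(1)))
  expect_equal(rej, 0.05, tolerance = 0.8) # 0.05 +/- 0.04
})

test_that("strong heteroscedasticity drives W down and p small", {
  set.seed(24)
  m <- matrix(rnorm(60 * 4), 60, 4)
  m[, 4] <- m[, 4] * 6
  res <- mauchly_test(m)
  expect_lt(res$w, 0.7)
  expect_lt(res$p, 0.01)
})

test_that("singular contrast covariance is flagged with W = 0", {
  m <- matrix(rnorm(5), 5, 1)
  m <- cbind(m, m, m) # all conditions identical per subject
  res <- mauchly_test(m)
  expect_true(res$singular)
  expect_equal(res$w, 0)
  expect_equal(res$p, 0)
})

test_that("lower-bound correction uses epsilon = 1/(k-1) and is conservative", {
  set.seed(25)
  m6 <- matrix(rnorm(10 * 6), 10, 6)
  res <- rm_anova(m6, correct = "none")
  expect_equal(res$epsilon_lower_bound, 0.2) # k = 6
  corr <- lower_bound_correct(res)
  expect_true(corr$sphericity_violated)
  expect_gte(corr$p_corrected, res$p)
  # k = 2: epsilon = 1, p unchanged
  m2 <- matrix(rnorm(10 * 2), 10, 2)
  res2 <- lower_bound_correct(rm_anova(m2, correct = "none"))
  expect_equal(res2$epsilon_lower_bound, 1)
  expect_equal(res2$p_corrected, res2$p)
  # property sweep: corrected p >= p on any input
  for (i in 1:10) {
    m <- matrix(rnorm(8 * 4, sd = runif(1, 0.5, 2)), 8, 4)
    r <- rm_anova(m, correct = "none")
    expect_gte(lower_bound_correct(r)$p_corrected, r$p)
  }
})

test_that("auto correction engages only when sphericity is rejected", {
  set.seed(26)
  m <- matrix(rnorm(40 * 4), 40, 4)
  m[, 4] <- m[, 4] * 8 # blatant violation
  res <- rm_anova(m, correct = "auto")
  expect_true(res$sphericity_violated)
  expect_gte(res$p_corrected, res$p)
})

test_that("between-vs-within F test has power and handles degeneracy", {
  # strong subject effect -> tiny p
  cs <- cohort_spec(n_subjects = 10, sigma_b = 0.050, sigma_w = 0.002,
                    seed = 41)
  m <- roi_matrix(simulate_roi_table(cs, c(r = 0.1)))
  res <- between_vs_within_test(m)
  expect_lt(res$p, 1e-6)
  expect_equal(res$df, c(9, 50))
  # identical subjects and repetitions -> degenerate
  res0 <- between_vs_within_test(matrix(1, 4, 3))
  expect_true(res0$degenerate)
})

test_that("between-vs-within type-I error is near nominal under the null", {
  set.seed(27)
  rej <- mean(vapply(1:400, function(i) {
    between_vs_within_test(matrix(rnorm(10 * 6), 10, 6))$p < 0.05
  }, logical(1)))
  expect_equal(rej, 0.05, tolerance = 0.8) # 5% +/- ~4 points
})

test_that("pairwise method differences: identity, offset, antisymmetry", {
  cs <- cohort_spec(n_subjects = 8, seed = 51)
  base <- simulate_roi_table(cs, c(a = 0.05, b = -0.02), method = "m1")
  dup <- base
  dup$method <- "m2"
  shift <- base
  shift$method <- "m3"
  shift$chi_ppm <- shift$chi_ppm + 0.010 # +10 ppb constant offset
  res <- pairwise_method_diffs(dplyr::bind_rows(base, dup, shift))
  for (roi in names(res)) {
    m <- res[[roi]]
    # duplicated method: zero difference, flagged not significant
    expect_equal(m$diff_ppb["m1", "m2"], 0)
    expect_true(m$not_significant["m1", "m2"])
    # constant offset: 10 ppb, significant
    expect_equal(m$diff_ppb["m3", "m1"], 10, tolerance = 1e-9)
    expect_false(m$not_significant["m3", "m1"])
    # antisymmetry, zero diagonal
    expect_equal(m$diff_ppb, -t(m$diff_ppb))
    expect_true(all(diag(m$diff_ppb) == 0))
    expect_true(all(diag(m$not_significant)))
  }
})

test_that("pairwise comparison rejects mismatched subjects", {
  cs <- cohort_spec(n_subjects = 4, seed = 52)
  a <- simulate_roi_table(cs, c(r = 0.1), method = "m1")
  b <- simulate_roi_table(cs, c(r = 0.1), method = "m2")
  b <- b[b$subject != 4, ]
  expect_error(pairwise_method_diffs(dplyr::bind_rows(a, b)),
               "same subjects")
})

test_that("Bonferroni correction only raises pairwise p-values", {
  cs <- cohort_spec(n_subjects = 6, seed = 53)
  tabs <- dplyr::bind_rows(lapply(1:3, function(i) {
    t <- simulate_roi_table(cs, c(r = 0.05), method = paste0("m", i),
                            seed = 60 + i)
    t
  }))
  plain <- pairwise_method_diffs(tabs)
  bonf <- pairwise_method_diffs(tabs, bonferroni = TRUE)
  expect_true(all(bonf$r$p >= plain$r$p))
})

test_that("RANOVA type-I error is near nominal and lower bound conservative", {
  set.seed(28)
  p_raw <- numeric(300)
  p_corr <- numeric(300)
  for (i in 1:300) {
    m <- matrix(rnorm(10 * 6), 10, 6)
    r <- rm_anova(m, correct = "none")
    p_raw[i] <- r$p
    p_corr[i] <- lower_bound_correct(r)$p_corrected
  }
  expect_equal(mean(p_raw < 0.05), 0.05, tolerance = 0.9)
  expect_lte(mean(p_corr < 0.05), 0.05)
})
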