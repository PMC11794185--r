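test_that("exact signed-rank p-values match exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, 0.2, 1), 3)
    shift <- sample(c(0, 0.1, -0.3), 1)
    if (any(d == shift) || anyDuplicated(abs(d - shift)) > 0) next
    mine <- wilcoxon_signed_rank(d, shift)
    oracle <- enum_signed_rank(d, shift)
    expect_true(mine$exact)
    expect_equal(mine$statistic, oracle$statistic)
    expect_equal(mine$p_greater, oracle$p_greater, tolerance = 1e-12)
    expect_equal(mine$p_less, oracle$p_less, tolerance = 1e-12)
    expect_equal(mine$p_two_sided, oracle$p_two_sided, tolerance = 1e-12)
  }
  # the spec'd 8-difference example
  d8 <- c(1.1, -0.3, 0.7, 2.0, -0.2, 0.9, 1.4, 0.5)
  expect_equal(wilcoxon_signed_rank(d8)$p_two_sided,
               enum_signed_rank(d8)$p_two_sided, tolerance = 1e-12)
})

test_that("signed-rank p-values agree with stats::wilcox.test conventions", {
  set.seed(32)
  # exact branch
  d <- rnorm(15)
  mine <- wilcoxon_signed_rank(d, shift = 0.1)
  expect_equal(mine$p_greater,
               wilcox.test(d, mu = 0.1, alternative = "greater")$p.value)
  expect_equal(mine$p_two_sided, wilcox.test(d, mu = 0.1)$p.value)
  # normal-approximation branch with continuity correction
  d2 <- rnorm(60)
  mine2 <- wilcoxon_signed_rank(d2, shift = -0.05)
  expect_equal(mine2$p_less,
               wilcox.test(d2, mu = -0.05, alternative = "less")$p.value)
  expect_equal(mine2$p_two_sided, wilcox.test(d2, mu = -0.05)$p.value)
  # tie-corrected path
  d3 <- round(rnorm(40), 1)
  d3 <- d3[d3 != 0]
  mine3 <- wilcoxon_signed_rank(d3)
  ref3 <- suppressWarnings(wilcox.test(d3, exact = FALSE))
  expect_equal(mine3$p_two_sided, ref3$p.value)
})

test_that("an all-positive sample attains the smallest one-sided p", {
  w <- wilcoxon_signed_rank(rep(1, 20) + 0.5, shift = 0.5)
  expect_equal(w$statistic, 20 * 21 / 2)
  expect_equal(w$p_greater, 2^-20)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(wilcoxon_signed_rank(rep(0.3, 10), shift = 0.3), "degenerate")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3)), "at least 5")
})

test_that("TOST verdicts behave at and far from the bounds", {
  a <- seq(0.40, 0.50, length.out = 50)
  # constant +0.001 S/m offset: well within +-0.05, equivalent (and, being
  # perfectly consistent, also 'different' -- the verdicts are not exclusive)
  r1 <- tost_equivalence(a + 0.001, a)
  expect_true(r1$equivalent)
  expect_true(r1$different)
  expect_equal(r1$median_diff, 0.001)
  # constant +0.2 S/m offset: far outside the bounds
  r2 <- tost_equivalence(a + 0.2, a)
  expect_false(r2$equivalent)
  expect_true(r2$different)
  expect_error(tost_equivalence(a, a[-1]), "equal length")
})

test_that("widening the bounds never revokes equivalence", {
  set.seed(33)
  for (rep in 1:20) {
    d <- rnorm(40, mean = runif(1, -0.06, 0.06), sd = 0.03)
    a <- rnorm(40, 0.4, 0.01)
    verdicts <- vapply(c(0.02, 0.05, 0.10), function(b) {
      tost_equivalence(a + d, a, bounds = c(-b, b))$equivalent
    }, logical(1))
    expect_true(all(diff(as.integer(verdicts)) >= 0))
  }
})

test_that("equivalence claims stay near level alpha at a true bound", {
  set.seed(34)
  hits <- vapply(seq_len(1000), function(i) {
    d <- rnorm(50, mean = 0.05, sd = 0.01) # offset exactly at upper bound
    b <- rnorm(50, 0.4, 0.005)
    tost_equivalence(b + d, b)$equivalent
  }, logical(1))
  expect_lt(mean(hits), 0.05 + 0.02)
})

test_that("unpaired mode uses the rank-sum procedure", {
  set.seed(35)
  a <- rnorm(40, 0.40, 0.01)
  b <- rnorm(45, 0.401, 0.01)
  r <- tost_equivalence(a, b, paired = FALSE)
  expect_true(r$equivalent)
  expect_equal(r$p_lower,
               wilcox.test(a, b, mu = -0.05, alternative = "greater")$p.value)
})

test_that("the roster runner validates inputs and handles empty rosters", {
  tab <- data.frame(subject = rep(paste0("s", 1:6), 2),
                    model = "smt",
                    roi_name = rep(c("putamen_left", "putamen_right"),
                                   each = 6),
                    median = c(0.40, 0.41, 0.42, 0.39, 0.40, 0.43,
                               0.41, 0.40, 0.43, 0.40, 0.39, 0.41))
  empty <- run_comparison_roster(tab, data.frame(roi_a = character(),
                                                 roi_b = character()))
  expect_equal(nrow(empty), 0)
  expect_error(run_comparison_roster(tab, data.frame(roi_a = "putamen_left",
                                                     roi_b = "no_such")),
               "absent")
  one <- run_comparison_roster(tab, data.frame(roi_a = "putamen_left",
                                               roi_b = "putamen_right"))
  expect_equal(nrow(one), 1)
  expect_equal(one$n, 6)
})
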