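# FAC2, MAPE, Spearman, fractional bias, Wilcoxon signed-rank, summaries.

test_that("FAC2 includes both factor-of-two boundaries and excludes zero observations", {
  expect_equal(fac2(c(1, 2, 3), c(1, 2, 3))$fac2, 1)
  r <- fac2(c(1, 2, 10), c(2, 2, 2))
  expect_equal(r$fac2, 2 / 3)            # ratios 0.5, 1, 5
  expect_equal(fac2(4, 2)$fac2, 1)       # ratio exactly 2.0 included
  expect_equal(fac2(1, 2)$fac2, 1)       # ratio exactly 0.5 included
  expect_equal(fac2(4.001, 2)$fac2, 0)
  z <- fac2(c(1, 5), c(0, 5))
  expect_equal(z$n_used, 1L)
  expect_equal(z$n_excluded_zero_observed, 1L)
  expect_true(is.na(fac2(1, 0)$fac2))
  # invariant to pair order
  set.seed(3)
  p <- runif(20); o <- runif(20)
  perm <- sample(20)
  expect_equal(fac2(p, o)$fac2, fac2(p[perm], o[perm])$fac2)
})

test_that("MAPE removes zero predictions and zero observations, with counts", {
  r <- mape(c(2, 0, 3), c(4, 5, 3))
  expect_equal(r$mape, 0.25)  # (0.5 + 0) / 2
  expect_equal(r$n_used, 2L)
  expect_equal(r$n_excluded_zero_predicted, 1L)
  expect_equal(mape(c(1, 2), c(1, 2))$mape, 0)
  expect_equal(mape(3, 2)$mape, 0.5)
  expect_true(is.na(mape(0, 5)$mape))
  # scale invariance under common positive scaling
  set.seed(4)
  p <- runif(15, 1, 5); o <- runif(15, 1, 5)
  expect_equal(mape(p, o)$mape, mape(7 * p, 7 * o)$mape)
})

test_that("Spearman is the Pearson correlation of mid-ranks", {
  expect_equal(spearmanRho(c(1, 5, 9), c(2, 3, 40))$rho, 1)
  expect_equal(spearmanRho(c(9, 5, 1), c(2, 3, 40))$rho, -1)
  # tie case against a hand mid-rank computation
  p <- c(1, 2, 2, 4); o <- c(1, 3, 2, 4)
  want <- cor(rank(p), rank(o))  # mid-ranks: 1, 2.5, 2.5, 4
  expect_equal(spearmanRho(p, o)$rho, want)
  const <- spearmanRho(c(2, 2, 2), c(1, 2, 3))
  expect_true(is.na(const$rho) && const$constant)
})

test_that("fractional bias follows the 1/n definition and is antisymmetric", {
  expect_equal(fractionalBias(c(3, 3), c(3, 3))$fb, 0)
  expect_equal(fractionalBias(c(4, 2), c(2, 2))$fb, 0.2)  # (1/2)(2/5)
  expect_equal(fractionalBias(3, 1)$fb, 1)                # n = 1: 2/2
  a <- c(5, 2, 8); b <- c(1, 4, 6)
  expect_equal(fractionalBias(a, b)$fb, -fractionalBias(b, a)$fb)
  # conventional form drops the 1/n
  expect_equal(fractionalBias(c(4, 2), c(2, 2), standard = TRUE)$fb, 0.4)
  u <- fractionalBias(c(0, 0), c(0, 0))
  expect_true(is.na(u$fb) && u$undefined)
})

test_that("Wilcoxon signed-rank: degeneracy, antisymmetry, exact enumeration", {
  d <- wilcoxonSignedRank(c(1, 2, 3), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_equal(d$z, 0)
  expect_equal(d$p, 1)

  set.seed(19)
  a <- rnorm(9, 1); b <- rnorm(9)
  w1 <- wilcoxonSignedRank(a, b)
  w2 <- wilcoxonSignedRank(b, a)
  expect_equal(w1$z, -w2$z)
  expect_equal(w1$p, w2$p)

  # exact p equals the exhaustive 2^n sign-enumeration oracle
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    a <- round(rnorm(n, 0.4), 2); b <- round(rnorm(n), 2)
    got <- wilcoxonSignedRank(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$p, wilcoxonEnumP(a - b), tolerance = 1e-12)
  }
})

test_that("normal approximation is close to exact for n in 10..12", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(10:12, 1)
    a <- rnorm(n, 0.3); b <- rnorm(n)
    ex <- wilcoxonSignedRank(a, b, exact = TRUE)
    ap <- wilcoxonSignedRank(a, b, exact = FALSE)
    expect_lt(abs(ap$p - ex$p), 0.02)
  }
})

test_that("Wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(37)
  a <- rnorm(40, 0.5); b <- rnorm(40)
  got <- wilcoxonSignedRank(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("Pratt zero handling shifts the null but stays sane", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- c(1, 2, 3, 1, 1, 1, 1, 20)  # three zero differences
  drop <- wilcoxonSignedRank(a, b, zeroes = "drop")
  pratt <- wilcoxonSignedRank(a, b, zeroes = "pratt")
  expect_equal(drop$n_nonzero, 5L)
  expect_equal(pratt$n_nonzero, 5L)
  expect_false(isTRUE(all.equal(drop$z, pratt$z)))
  expect_true(pratt$p >= 0 && pratt$p <= 1)
})

test_that("agreement summaries preserve totals and strata", {
  cls <- c("both_zero", "both_zero", "both_zero", "fp_high", "fp_high")
  t1 <- agreementSummary(cls)
  expect_equal(unname(t1[["both_zero"]]), 3L)
  expect_equal(unname(t1[["fp_high"]]), 2L)
  expect_equal(sum(t1), length(cls))
  st <- c("OH", "OH", "PA", "PA", "PA")
  t2 <- agreementSummary(cls, st)
  expect_equal(sum(t2), 5L)
  expect_equal(unname(t2["fp_high", "PA"]), 2L)
  t0 <- agreementSummary(character(0))
  expect_equal(sum(t0), 0L)
})

test_that("metricsReport bundles the statistics coherently", {
  set.seed(53)
  p <- rpois(30, 20); o <- rpois(30, 20)
  rep <- metricsReport(p, o, agreement = rep("both_positive", 30))
  expect_s4_class(rep, "MetricsReport")
  expect_equal(rep@fac2, fac2(p, o)$fac2)
  expect_equal(rep@mape, mape(p, o)$mape)
  expect_equal(rep@agreementCounts[["both_positive"]], 30L)
  expect_output(show(rep), "FAC2")
})
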