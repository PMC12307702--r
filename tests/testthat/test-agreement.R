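test_that("ICC matches an independent ANOVA oracle on small tables", {
  tables <- list(
    list(a = c(9, 2, 5, 8, 6, 7), b = c(2, 1, 2, 6, 1, 2)),
    list(a = c(1, 3, 5, 7, 9, 11), b = c(2, 4, 6, 8, 10, 12)),
    list(a = c(10.5, 12.1, 9.8, 14.2, 11.1, 13.3),
         b = c(10.9, 11.8, 10.2, 13.9, 11.6, 12.8))
  )
  for (tb in tables) {
    got <- icc_two_way_mixed_single(tb$a, tb$b, "consistency")
    ms <- anova_ms_oracle(tb$a, tb$b)
    expect_equal(got$icc, icc_consistency_oracle(tb$a, tb$b),
                 tolerance = 1e-10)
    expect_equal(got$f_value, ms$msr / ms$mse, tolerance = 1e-10)
    expect_equal(got$ms$msc, ms$msc, tolerance = 1e-10)
    abs_got <- icc_two_way_mixed_single(tb$a, tb$b, "absolute_agreement")
    n <- length(tb$a)
    expect_equal(abs_got$icc,
                 (ms$msr - ms$mse) /
                   (ms$msr + ms$mse + (2 / n) * (ms$msc - ms$mse)),
                 tolerance = 1e-10)
  }
})

test_that("ICC point estimates, F, p and CI match a reference oracle", {
  # fixture table with oracle values frozen from an independent
  # implementation of the two-way mixed single-measures ICC
  set.seed(3)
  a <- rnorm(12, 50, 10)
  b <- a + rnorm(12, 2, 6)
  cons <- icc_two_way_mixed_single(a, b, "consistency")
  abs_ <- icc_two_way_mixed_single(a, b, "absolute_agreement")
  expect_equal(cons$icc, 0.8922781891233937, tolerance = 1e-12)
  expect_equal(abs_$icc, 0.9003178004242449, tolerance = 1e-12)
  expect_equal(cons$f_value, 17.56634217086239, tolerance = 1e-12)
  expect_equal(cons$p_value, 2.0545715868011e-05, tolerance = 1e-9)
  expect_equal(round(cons$ci_low, 2), 0.67)
  expect_equal(round(cons$ci_high, 2), 0.97)
  expect_equal(round(abs_$ci_low, 2), 0.69)
  expect_equal(round(abs_$ci_high, 2), 0.97)
})

test_that("ICC handles identity, independence and degenerate inputs", {
  a <- c(4, 8, 15, 16, 23, 42)
  ident <- icc_two_way_mixed_single(a, a)
  expect_equal(ident$icc, 1)
  expect_equal(c(ident$ci_low, ident$ci_high), c(1, 1))

  set.seed(19)
  noise <- icc_two_way_mixed_single(rnorm(10000), rnorm(10000))
  expect_lt(abs(noise$icc), 0.05)

  expect_error(icc_two_way_mixed_single(1:2, 2:3), "at least 3")
  expect_error(icc_two_way_mixed_single(rep(1, 5), rep(1, 5)),
               "zero total variance")
  expect_error(icc_two_way_mixed_single(c(1, NA, 3), c(1, 2, 3)),
               "missing")
})

test_that("consistency ICC ignores a constant shift; absolute does not", {
  set.seed(23)
  a <- rnorm(50, 100, 15)
  b <- a + rnorm(50, 0, 4)
  shifted <- b + 20
  expect_equal(icc_two_way_mixed_single(a, shifted, "consistency")$icc,
               icc_two_way_mixed_single(a, b, "consistency")$icc,
               tolerance = 1e-12)
  expect_lt(
    icc_two_way_mixed_single(a, shifted, "absolute_agreement")$icc,
    icc_two_way_mixed_single(a, b, "absolute_agreement")$icc - 0.2)
  # affinely identical series: consistency 1, absolute below 1
  expect_equal(icc_two_way_mixed_single(a, a + 7, "consistency")$icc, 1)
  expect_lt(icc_two_way_mixed_single(a, a + 7, "absolute_agreement")$icc,
            1)
})

test_that("ICC recovers a known intraclass correlation in simulation", {
  rho <- 0.7
  set.seed(29)
  n <- 5000
  s <- rnorm(n, 0, sqrt(rho))
  a <- s + rnorm(n, 0, sqrt(1 - rho))
  b <- s + rnorm(n, 0, sqrt(1 - rho))
  expect_equal(icc_two_way_mixed_single(a, b)$icc, rho, tolerance = 0.03 / rho)
})

test_that("nonparametric Bland-Altman uses the median and percentiles", {
  x <- rnorm(30)
  ba0 <- bland_altman_nonparametric(x, x)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  ba5 <- bland_altman_nonparametric(x + 5, x)
  expect_equal(c(ba5$bias, ba5$loa_low, ba5$loa_high), c(5, 5, 5))

  # differences 1..100 under type-7 interpolation
  ba <- bland_altman_nonparametric(1:100 + 1000, rep(1000, 100))
  expect_equal(ba$bias, 50.5)
  expect_equal(ba$loa_low, 3.475)
  expect_equal(ba$loa_high, 97.525)
  expect_equal(ba$means, (1:100 + 2000) / 2)

  expect_error(bland_altman_nonparametric(1:3, 1:4), "equal length")
})

test_that("Bland-Altman limits bracket the bias and ~95% of differences", {
  set.seed(37)
  for (i in 1:10) {
    a <- rnorm(200, 10, 3)
    b <- a + rexp(200, 1 / 2) - 1   # skewed differences
    ba <- bland_altman_nonparametric(a, b)
    expect_lte(ba$loa_low, ba$bias)
    expect_gte(ba$loa_high, ba$bias)
    inside <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
    expect_gte(inside, 0.94)
    # equivariance under a constant added to the differences
    ba2 <- bland_altman_nonparametric(a + 3, b)
    expect_equal(ba2$bias, ba$bias + 3)
    expect_equal(ba2$loa_low, ba$loa_low + 3)
  }
})

test_that("Wilcoxon uses the exact distribution for small tie-free data", {
  # six all-positive differences: the most extreme of the 2^6 sign
  # patterns, exact two-sided p = 2/64
  a <- c(11, 22, 33, 44, 55, 66)
  b <- c(10, 20, 30, 40, 50, 60)
  w <- wilcoxon_signed_rank(a, b)
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$statistic, 0)
  expect_equal(w$n_effective, 6L)

  # independent check: enumerate all sign patterns of the rank sum
  d <- abs(a - b)
  r <- rank(d)
  wplus_all <- vapply(0:63, function(mask) {
    sum(r[bitwAnd(mask, bitwShiftL(1L, 0:5)) != 0L])
  }, 0)
  p_enum <- mean(wplus_all >= sum(r)) * 2
  expect_equal(w$p_value, p_enum)
})

test_that("Wilcoxon agrees with the stats implementation when tie-free", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(c(8, 15, 40), 1)
    a <- rnorm(n)
    b <- a + rnorm(n, 0.3)
    w <- wilcoxon_signed_rank(a, b)
    ref_p <- stats::wilcox.test(a, b, paired = TRUE, correct = FALSE,
                                exact = n <= 25)$p.value
    expect_equal(w$p_value, ref_p, tolerance = 1e-12)
    expect_identical(w$method, if (n <= 25) "exact" else "normal_approx")
  }
})

test_that("Wilcoxon handles zeros, ties and degenerate input", {
  # antisymmetric tied differences put the statistic dead centre: p = 1
  a <- c(1, -1, 2, -2, 3, -3)
  w <- wilcoxon_signed_rank(a, rep(0, 6))
  expect_identical(w$method, "normal_approx")
  expect_equal(w$p_value, 1)

  # zero differences are dropped but the rest can stay exact
  wz <- wilcoxon_signed_rank(c(0, 1, 2, 4) + c(5, 5, 5, 5),
                             c(5, 4, 3, 1))
  expect_equal(wz$n_effective, 3L)
  expect_identical(wz$method, "exact")

  wd <- wilcoxon_signed_rank(1:5, 1:5)
  expect_identical(wd$method, "degenerate")
  expect_equal(wd$p_value, 1)

  # exact and normal approximation agree closely at n = 25 on tie-free
  # data once outside the continuity-offset-dominated centre
  d <- (1:25) / 10
  signs <- ifelse(1:25 %in% c(3, 14:25), 1, -1)   # W+ = 237, z ~ 2
  b <- seq(100, 102, length.out = 25)
  a <- b + d * signs
  w <- wilcoxon_signed_rank(a, b)
  mu <- 25 * 26 / 4
  s2 <- 25 * 26 * 51 / 24
  z <- (w$w_plus - mu) / sqrt(s2)
  expect_lt(abs(w$p_value - 2 * pnorm(-abs(z))), 0.01)
})

test_that("agreement_report bundles all statistics coherently", {
  set.seed(47)
  a <- rpois(40, 200)
  b <- a + rpois(40, 6) - 3
  rep_ <- agreement_report(a, b, "demo")
  expect_s3_class(rep_$icc_consistency, "icc_result")
  expect_identical(rep_$icc_absolute$variant, "absolute_agreement")
  expect_equal(rep_$bland_altman$bias, median(a - b))
  expect_equal(rep_$n, 40L)
  lst <- ki67match:::agreement_report_to_list(rep_)
  expect_named(lst, c("label", "n", "icc_consistency", "icc_absolute",
                      "bland_altman", "wilcoxon"))
})
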