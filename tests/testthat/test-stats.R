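test_that("exact signed-rank p-values match small-sample enumeration", {
  # all five differences positive: one-sided p = 1/32, two-sided floor 1/16
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5), alternative = "greater")
  expect_equal(r$p_value, 0.03125)
  expect_equal(r$statistic, 15)
  r2 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5), alternative = "two.sided")
  expect_equal(r2$p_value, 0.0625)

  # identical samples -> p = 1 with a warning
  expect_warning(r3 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(r3$p_value, 1)
})

test_that("enumeration agrees with the brute-force oracle for n <= 10", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(2:10, 1)
    d <- round(rnorm(n, 0.2, 1), 1) # rounding makes ties and zeros likely
    if (all(d == 0)) d[1] <- 0.5
    alt <- sample(c("greater", "less", "two.sided"), 1)
    got <- suppressWarnings(wilcoxon_signed_rank(d, alternative = alt))$p_value
    expect_equal(got, signed_rank_brute(d, alt), info = paste(alt, toString(d)))
  }
  # and with the interface used by the pipeline (paired samples)
  x <- c(0.2, 0.25, 0.3, 0.22, 0.27)
  y <- c(0.18, 0.26, 0.24, 0.2, 0.22)
  expect_equal(wilcoxon_signed_rank(x, y, "greater")$p_value,
               signed_rank_brute(x - y, "greater"))
})

test_that("SPI-vs-1 test works in both modes", {
  expect_warning(p_unity <- spi_vs_one_test(rep(1, 5))$p_value, "zero")
  expect_equal(p_unity, 1)
  r <- spi_vs_one_test(c(1.05, 1.1, 1.2, 1.02, 1.3), alternative = "greater")
  expect_equal(r$p_value, 0.03125)

  # constant-reference U-test: all SPI > 1, n = 5 -> U = 25 (maximal)
  u <- spi_vs_one_test(c(1.05, 1.1, 1.2, 1.02, 1.3), mode = "utest",
                       alternative = "greater")
  expect_equal(u$statistic, 25)
  expect_lt(u$p_value, 0.05)
  ut <- spi_vs_one_test(rep(1, 4), mode = "utest")
  expect_equal(ut$statistic, 8) # all ties count 1/2
  expect_equal(ut$p_value, 1)

  expect_error(spi_vs_one_test(numeric(0)), "empty")
})

test_that("Feltz-Miller statistic follows the pooled-CV formula", {
  # identical values in both groups -> D = 0, p = 1
  r <- feltz_miller_cv_test(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # CV invariance: rescaling any group by a positive constant changes nothing
  set.seed(2)
  a <- rlnorm(40, 0, 0.2); b <- rlnorm(50, 0, 0.25)
  r1 <- feltz_miller_cv_test(list(a, b))
  r2 <- feltz_miller_cv_test(list(3.7 * a, b))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)

  # hand check of the statistic on summary stats
  ns <- c(40, 50); means <- c(2, 3); sds <- c(0.4, 0.9)
  cv <- sds / means; m <- ns - 1
  cbar <- sum(m * cv) / sum(m)
  D <- sum(m * (cv - cbar)^2) / (cbar^2 * (0.5 + cbar^2))
  r3 <- feltz_miller_cv_test(means = means, sds = sds, ns = ns)
  expect_equal(r3$statistic, D)
  expect_equal(r3$p_value, pchisq(D, 1, lower.tail = FALSE))

  expect_error(feltz_miller_cv_test(list(c(1, 2))), "at least 2")
  expect_error(feltz_miller_cv_test(list(c(-2, -3), c(1, 2))), "positive")
})

test_that("Feltz-Miller keeps its nominal size and has power", {
  # type-I error on identical lognormal populations (quick check; the
  # full-scale calibration runs in the acceptance suite)
  set.seed(11)
  nrep <- 2000; n <- 50
  x <- matrix(rlnorm(nrep * n, 0, 0.1), n)
  y <- matrix(rlnorm(nrep * n, 0, 0.1), n)
  p <- vapply(seq_len(nrep), function(k) {
    feltz_miller_cv_test(means = c(mean(x[, k]), mean(y[, k])),
                         sds = c(sd(x[, k]), sd(y[, k])), ns = c(n, n))$p_value
  }, 0)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)

  # power against a 2:1 CV ratio at n = 100
  s1 <- sqrt(log(1 + 0.1^2)); s2 <- sqrt(log(1 + 0.2^2))
  px <- vapply(1:1000, function(k) {
    g1 <- rlnorm(100, 0, s1); g2 <- rlnorm(100, 0, s2)
    feltz_miller_cv_test(list(g1, g2))$p_value
  }, 0)
  expect_gt(mean(px < 0.05), 0.9)
})

test_that("group significance maps flag designed effects only", {
  gs <- toy_group_stats(n_subj = 5, effect = 0.2)
  mp <- roi_significance_maps(gs, alpha = 0.05, n_grid = 3)
  expect_equal(mp$n_testable, 2)
  expect_true(mp$strain$flag[1, 1])   # amplified cell
  expect_false(mp$strain$flag[2, 1])  # null cell
  expect_true(mp$spi$flag[1, 1])
  expect_false(mp$spi$flag[2, 1])
  expect_equal(mp$strain$pct_significant, 50)

  # alpha = 0 -> no flags anywhere
  mp0 <- roi_significance_maps(gs, alpha = 0, n_grid = 3)
  for (f in c("strain", "spi", "shi")) expect_equal(sum(mp0[[f]]$flag), 0)

  # a cell missing for one subject is untestable
  gs2 <- gs[!(gs$subject == "S03" & gs$i == 1), ]
  mp2 <- roi_significance_maps(gs2, n_grid = 3)
  expect_false(mp2$testable[1, 1])
  expect_true(mp2$testable[2, 1])

  # Benjamini-Hochberg option only makes calls more conservative
  mpbh <- roi_significance_maps(gs, alpha = 0.05, n_grid = 3, p_adjust = "BH")
  expect_true(all(mpbh$strain$p[mpbh$testable] >= mp$strain$p[mp$testable]))
})

test_that("SHI family uses pooled per-tet moments and requires a CV increase", {
  gs <- toy_group_stats(n_subj = 5, effect = 0.2)
  # raw_sd at T3 was inflated only for the amplified cell
  mp <- roi_significance_maps(gs, alpha = 0.05, n_grid = 3)
  expect_true(mp$shi$flag[1, 1])
  expect_false(mp$shi$flag[2, 1])

  # pooled moments match pooling the raw samples
  set.seed(9)
  xs <- list(rnorm(50, 1.2, 0.1), rnorm(80, 1.25, 0.15), rnorm(30, 1.1, 0.05))
  pm <- lungstrain:::pooled_moments(vapply(xs, length, 0L),
                                    vapply(xs, mean, 0),
                                    vapply(xs, sd, 0))
  expect_equal(pm$mean, mean(unlist(xs)))
  expect_equal(pm$sd, sd(unlist(xs)))
})
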