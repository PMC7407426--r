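# Per-ROI statistical battery: exact Wilcoxon signed-rank (full enumeration
# of the 2^n sign assignments), a one-sample location test of SPI against
# 1.0, a Mann-Whitney-vs-constant variant, and the Feltz-Miller asymptotic
# test for equality of coefficients of variation across k populations.

test_result <- function(statistic, p_value, n, sidedness, method) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 sidedness = sidedness, method = method),
            class = "lung_test_result")
}

#' @export
print.lung_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.5g (n = %s, %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/"), x$sidedness))
  invisible(x)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired test on `x_t3 - x_t1` (or a one-sample test when `y` is omitted).
#' Zero differences are dropped (Wilcoxon convention), ties get mid-ranks,
#' and for n <= 25 the p-value comes from full enumeration of all 2^n sign
#' assignments, which remains exact under ties; larger n falls back to the
#' normal approximation with tie correction.
#'
#' @param x Values at the second condition (e.g. T3), or the differences
#'   when `y` is `NULL`.
#' @param y Values at the first condition (e.g. T1), paired with `x`.
#' @param alternative `"greater"` (x tends above y), `"less"`, or
#'   `"two.sided"`.
#' @return A test result with statistic `W` (sum of positive ranks),
#'   `p_value`, `n` (non-zero differences).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero")
    return(test_result(0, 1, 0, alternative, "exact Wilcoxon signed-rank"))
  }
  r <- rank(abs(d)) # mid-ranks for ties
  w_pos <- sum(r[d > 0])
  if (n <= 25) {
    enum <- signed_rank_enumerate_cpp(2 * r, 2 * w_pos)
    p <- switch(alternative,
                greater = enum$n_ge / enum$n_total,
                less = enum$n_le / enum$n_total,
                two.sided = min(1, enum$n_two / enum$n_total))
    method <- "exact Wilcoxon signed-rank"
  } else {
    mu <- sum(r) / 2
    tie_tab <- table(r)
    sigma2 <- sum(r^2) / 4
    z_g <- (w_pos - mu - 0.5) / sqrt(sigma2)
    z_l <- (w_pos - mu + 0.5) / sqrt(sigma2)
    p <- switch(alternative,
                greater = pnorm(z_g, lower.tail = FALSE),
                less = pnorm(z_l),
                two.sided = min(1, 2 * min(pnorm(z_g, lower.tail = FALSE), pnorm(z_l))))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  test_result(w_pos, p, n, alternative, method)
}

#' Test whether SPI differs from 1
#'
#' Default mode is a one-sample exact signed-rank test on `SPI - 1`: testing
#' a sample against the constant 1.0 makes a two-sample rank test
#' degenerate, so the paired location test is the better-behaved analogue.
#' The `"utest"` mode nevertheless runs a Mann-Whitney U of the SPI sample
#' against a same-length constant-1 sample, with the U statistic counted
#' directly (ties count 1/2) and the tie-corrected normal approximation for
#' the p-value.
#'
#' @param spi_values Per-subject SPI values for one ROI.
#' @param mode `"signed_rank"` (default) or `"utest"`.
#' @param alternative Sidedness, default `"greater"` (progression).
#' @return A test result (statistic is W or U depending on mode).
#' @export
spi_vs_one_test <- function(spi_values, mode = c("signed_rank", "utest"),
                            alternative = c("greater", "less", "two.sided")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  spi_values <- spi_values[!is.na(spi_values)]
  if (length(spi_values) == 0) stop("empty SPI sample")
  if (mode == "signed_rank") {
    res <- wilcoxon_signed_rank(spi_values - 1, alternative = alternative)
    res$method <- "exact signed-rank of SPI vs 1"
    return(res)
  }
  ref <- rep(1, length(spi_values))
  u <- sum(outer(spi_values, ref, ">")) + 0.5 * sum(outer(spi_values, ref, "=="))
  p <- suppressWarnings(stats::wilcox.test(spi_values, ref,
                                           alternative = alternative,
                                           exact = FALSE, correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1 # fully tied samples
  test_result(u, p, length(spi_values), alternative,
              "Mann-Whitney U of SPI vs constant 1")
}

#' Feltz-Miller test for equality of coefficients of variation
#'
#' Asymptotic k-sample test. With per-group CV estimates `c_j = s_j / m_j`
#' and weights `m_j = n_j - 1`, the pooled CV is
#' `cbar = sum(m_j c_j) / sum(m_j)` and
#' `D = sum(m_j (c_j - cbar)^2) / (cbar^2 (0.5 + cbar^2))`
#' is referred to a chi-square with k - 1 degrees of freedom.
#'
#' @param samples List of k numeric vectors (positive-shifted values, e.g.
#'   1 + strain per tet), or `NULL` when summary statistics are supplied.
#' @param means,sds,ns Optional summary-statistic interface (per-group mean,
#'   SD, size) used instead of `samples`.
#' @return A test result with statistic `D`, `p_value`, per-group `n`, and
#'   the group CVs in `$cv`.
#' @export
feltz_miller_cv_test <- function(samples = NULL, means = NULL, sds = NULL, ns = NULL) {
  if (!is.null(samples)) {
    stopifnot(is.list(samples))
    ns <- vapply(samples, length, 0L)
    means <- vapply(samples, mean, 0)
    sds <- vapply(samples, sd, 0)
  }
  k <- length(ns)
  if (k < 2) stop("need at least 2 groups")
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(means <= 0)) stop("group means must be positive for a CV test")
  cv <- sds / means
  m <- ns - 1
  cbar <- sum(m * cv) / sum(m)
  if (cbar == 0) {
    warning("all coefficients of variation are zero")
    res <- test_result(0, 1, ns, "two.sided", "Feltz-Miller CV equality")
    res$cv <- cv
    return(res)
  }
  D <- sum(m * (cv - cbar)^2) / (cbar^2 * (0.5 + cbar^2))
  p <- pchisq(D, df = k - 1, lower.tail = FALSE)
  res <- test_result(D, p, ns, "two.sided", "Feltz-Miller CV equality")
  res$cv <- cv
  res
}

#' Per-ROI significance maps for a group
#'
#' Applies the three test families of the regional analysis to the per-cell
#' statistics of one group (all subjects, both times):
#' \describe{
#'   \item{strain}{T1 vs T3 Wilcoxon signed-rank on subject-level ROI mean
#'     strains.}
#'   \item{spi}{SPI vs 1.0 on subject-level per-cell SPIs.}
#'   \item{shi}{T1 vs T3 Feltz-Miller CV test on the per-tet (1 + strain)
#'     samples pooled across the group's subjects; flagged when p < alpha
#'     and the pooled CV increased.}
#' }
#' A cell is testable only if occupied for every subject at both times;
#' cells with fewer than 2 usable subjects are untestable.
#'
#' @param group_stats Data frame of per-cell stats for one group: columns
#'   subject, time (`"T1"`/`"T3"`), i, j, occupied, mean, sd, raw_n,
#'   raw_mean, raw_sd (as produced by [run_subject()]).
#' @param alpha Significance level (default 0.05).
#' @param sidedness Alternative for the progression tests (default
#'   `"greater"`; with n = 5 pairs the exact two-sided signed-rank floor is
#'   0.0625, so two-sided calls can never reach 0.05).
#' @param spi_mode Mode for [spi_vs_one_test()].
#' @param n_grid Grid size (default 10).
#' @param p_adjust Multiple-testing correction across cells per family:
#'   `"none"` (default, per-ROI tests at alpha as reported) or any
#'   [stats::p.adjust()] method such as `"BH"`.
#' @return A `significance_maps` list: per family a list with `p` and `flag`
#'   matrices, plus `testable` (logical matrix), `n_testable` and
#'   `pct_significant` per family.
#' @export
roi_significance_maps <- function(group_stats, alpha = 0.05,
                                  sidedness = "greater",
                                  spi_mode = "signed_rank", n_grid = 10L,
                                  p_adjust = "none") {
  stopifnot(alpha >= 0, alpha < 1)
  subjects <- unique(group_stats$subject)
  if (length(subjects) < 2) stop("need at least 2 subjects for group maps")
  p_strain <- p_spi <- p_shi <- matrix(NA_real_, n_grid, n_grid)
  cv_up <- matrix(FALSE, n_grid, n_grid)
  testable <- matrix(FALSE, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      cell <- group_stats[group_stats$i == i & group_stats$j == j &
                            group_stats$occupied, , drop = FALSE]
      t1 <- cell[cell$time == "T1", ]
      t3 <- cell[cell$time == "T3", ]
      common <- intersect(t1$subject, t3$subject)
      if (length(common) < length(subjects) || length(common) < 2) next
      testable[i, j] <- TRUE
      t1 <- t1[match(common, t1$subject), ]
      t3 <- t3[match(common, t3$subject), ]
      p_strain[i, j] <- wilcoxon_signed_rank(t3$mean, t1$mean,
                                             alternative = sidedness)$p_value
      spi_vals <- spi(t1$mean, t3$mean)
      p_spi[i, j] <- spi_vs_one_test(spi_vals, mode = spi_mode,
                                     alternative = sidedness)$p_value
      # pooled per-tet moments of (1 + strain) per time
      pool <- function(tt) pooled_moments(tt$raw_n, tt$raw_mean, tt$raw_sd)
      m1 <- pool(t1); m3 <- pool(t3)
      fm <- feltz_miller_cv_test(means = c(m1$mean, m3$mean),
                                 sds = c(m1$sd, m3$sd), ns = c(m1$n, m3$n))
      p_shi[i, j] <- fm$p_value
      cv_up[i, j] <- fm$cv[2] > fm$cv[1]
    }
  }
  n_testable <- sum(testable)
  fam <- function(p, extra = TRUE) {
    if (p_adjust != "none") {
      p[testable] <- stats::p.adjust(p[testable], method = p_adjust)
    }
    flag <- !is.na(p) & p < alpha & extra
    list(p = p, flag = flag,
         pct_significant = if (n_testable > 0) percentage_significant(flag, n_testable) else NA_real_)
  }
  structure(list(strain = fam(p_strain), spi = fam(p_spi),
                 shi = fam(p_shi, cv_up),
                 testable = testable, n_testable = n_testable, alpha = alpha,
                 sidedness = sidedness),
            class = "significance_maps")
}

# combine per-subject sample moments into pooled-sample moments
pooled_moments <- function(n, mean, sd) {
  N <- sum(n)
  gm <- sum(n * mean) / N
  ss <- sum((n - 1) * sd^2) + sum(n * (mean - gm)^2)
  list(n = N, mean = gm, sd = sqrt(ss / (N - 1)))
}

#' @export
print.significance_maps <- function(x, ...) {
  cat(sprintf("<significance_maps> %d testable cells (alpha = %g, %s)\n",
              x$n_testable, x$alpha, x$sidedness))
  for (f in c("strain", "spi", "shi")) {
    cat(sprintf("  %-6s: %d significant (%.1f%%)\n", f, sum(x[[f]]$flag),
                x[[f]]$pct_significant))
  }
  invisible(x)
}
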