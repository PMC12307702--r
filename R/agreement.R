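#' Intraclass correlation, two-way mixed model, single measures
#'
#' Quantifies agreement between two paired series (e.g. per-ROI cell
#' counts from the reference standard and from a detector) with the
#' single-measures intraclass correlation coefficient of the two-way
#' mixed ANOVA model: the n paired units are random targets, the two
#' sources are fixed raters. With mean squares for targets (`MSR`),
#' raters (`MSC`) and residual (`MSE`) from the two-way decomposition and
#' `k = 2` raters:
#'
#' * consistency (ICC(3,1)): `(MSR - MSE) / (MSR + (k-1) MSE)` — blind to
#'   a systematic shift between the raters;
#' * absolute agreement (ICC(A,1)): `(MSR - MSE) /
#'   (MSR + (k-1) MSE + k/n (MSC - MSE))` — penalises it.
#'
#' The 95% confidence interval follows the Shrout-Fleiss / McGraw-Wong
#' F-bounds (for the consistency form the two parameterizations
#' coincide); the p-value tests ICC = 0 via `F = MSR/MSE` with
#' `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param a,b Equal-length numeric vectors, `n >= 3`, no missing values.
#' @param variant `"consistency"` (default) or `"absolute_agreement"`.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `f_value`, `df1`, `df2`, `p_value`, `variant`, `n`, `k` and the mean
#'   squares `ms`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(40, 100, 20)
#' icc_two_way_mixed_single(truth + rnorm(40, 0, 5), truth + rnorm(40, 0, 5))
#' @export
icc_two_way_mixed_single <- function(a, b,
                                     variant = c("consistency",
                                                 "absolute_agreement"),
                                     conf_level = 0.95) {
  variant <- match.arg(variant)
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed",
                                 call. = FALSE)
  y <- cbind(as.numeric(a), as.numeric(b))
  k <- 2L
  g <- mean(y)
  rmeans <- rowMeans(y)
  cmeans <- colMeans(y)
  if (sum((y - g)^2) == 0) {
    stop("zero total variance: the intraclass correlation is undefined",
         call. = FALSE)
  }
  msr <- k * sum((rmeans - g)^2) / (n - 1)
  msc <- n * sum((cmeans - g)^2) / (k - 1)
  mse <- sum((y - outer(rmeans, rep(1, k)) -
                outer(rep(1, n), cmeans) + g)^2) / ((n - 1) * (k - 1))
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  f_value <- if (mse > 0) msr / mse else Inf
  p_value <- stats::pf(f_value, df1, df2, lower.tail = FALSE)
  alpha <- 1 - conf_level
  if (variant == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse > 0) {
      fl <- f_value / stats::qf(1 - alpha / 2, df1, df2)
      fu <- f_value * stats::qf(1 - alpha / 2, df2, df1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      ci <- c(1, 1)
    }
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (abs(1 - icc) < 1e-15) {
      ci <- c(1, 1)
    } else {
      aa <- (k * icc) / (n * (1 - icc))
      bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      num <- (aa * msc + bb * mse)^2
      den <- (aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1))
      v <- if (den > 0) num / den else k - 1
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(lo, hi)
    }
  }
  ci <- pmin(pmax(ci, -1), 1)
  structure(
    list(icc = icc, ci_low = min(ci[1], icc), ci_high = max(ci[2], icc),
         f_value = f_value, df1 = df1, df2 = df2, p_value = p_value,
         variant = variant, n = n, k = k,
         ms = list(msr = msr, msc = msc, mse = mse),
         conf_level = conf_level),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result> ICC(%s, single) = %.3f (%d%% CI %.3f-%.3f), F(%d,%d) = %.3g, p = %.4g, n = %d\n",
    if (x$variant == "consistency") "3,1" else "A,1", x$icc,
    round(100 * x$conf_level), x$ci_low, x$ci_high, x$df1, x$df2,
    x$f_value, x$p_value, x$n))
  invisible(x)
}

#' Nonparametric Bland-Altman agreement summary
#'
#' Bland-Altman analysis of two paired series using rank-based summaries,
#' appropriate when the paired differences are not normally distributed:
#' the bias is the *median* of the differences and the limits of
#' agreement are the 2.5th and 97.5th percentiles of the differences
#' (linear interpolation between closest order statistics, the usual
#' "type 7" definition of [stats::quantile()]).
#'
#' Differences are oriented `a - b`. Pass the reference standard as `a`
#' and the tool as `b`, so that over-estimation by the tool shows up as
#' negative differences.
#'
#' @param a,b Equal-length numeric vectors, `n >= 2`.
#' @return An object of class `bland_altman_result`: `bias`, `loa_low`,
#'   `loa_high`, plus the per-pair `means` and `diffs` series for
#'   plotting.
#' @export
bland_altman_nonparametric <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed",
                                 call. = FALSE)
  diffs <- as.numeric(a) - as.numeric(b)
  means <- (as.numeric(a) + as.numeric(b)) / 2
  loa <- stats::quantile(diffs, c(0.025, 0.975), type = 7, names = FALSE)
  structure(
    list(bias = stats::median(diffs), loa_low = loa[1], loa_high = loa[2],
         means = means, diffs = diffs, n = length(diffs)),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "<bland_altman_result> bias (median diff) %.4g, limits of agreement [%.4g, %.4g], n = %d\n",
    x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test on `a - b`. Zero differences are
#' dropped (standard signed-rank practice) and `n_effective` reports the
#' remaining pairs. With `n_effective <= 25` and no tied absolute
#' differences the exact null distribution of the rank sum is used;
#' otherwise a tie-corrected normal approximation without continuity
#' correction. The reported `statistic` is the smaller of the positive
#' and negative signed-rank sums.
#'
#' @param a,b Equal-length numeric vectors.
#' @return An object of class `wilcoxon_result`: `statistic`, `w_plus`,
#'   `n_effective`, `p_value`, `method` (`"exact"`, `"normal_approx"` or
#'   `"degenerate"` when all differences are zero, which gives p = 1).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  d <- as.numeric(a) - as.numeric(b)
  if (anyNA(d)) stop("missing values are not allowed", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(
      list(statistic = 0, w_plus = 0, n_effective = 0L, p_value = 1,
           method = "degenerate"),
      class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- n * (n + 1) / 2 - w_plus
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    method <- "exact"
    p <- 2 * min(stats::psignrank(w_plus, n),
                 stats::psignrank(w_plus - 1, n, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    method <- "normal_approx"
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w_plus - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(
    list(statistic = min(w_plus, w_minus), w_plus = w_plus,
         n_effective = n, p_value = p, method = method),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "<wilcoxon_result> W = %g (smaller rank sum), n_eff = %d, p = %.4g (%s)\n",
    x$statistic, x$n_effective, x$p_value, x$method))
  invisible(x)
}

#' Full agreement report for one paired series
#'
#' Bundles the agreement statistics computed for each detector-vs-
#' reference comparison: the intraclass correlation in both the
#' consistency and absolute-agreement variants, the nonparametric
#' Bland-Altman summary and the paired Wilcoxon signed-rank test.
#' Differences are oriented reference minus tool (`a - b`).
#'
#' @param a Reference series.
#' @param b Tool series, same length.
#' @param label Optional name of the comparison.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(a, b, label = "comparison") {
  structure(
    list(label = label, n = length(a),
         icc_consistency = icc_two_way_mixed_single(a, b, "consistency"),
         icc_absolute = icc_two_way_mixed_single(a, b,
                                                 "absolute_agreement"),
         bland_altman = bland_altman_nonparametric(a, b),
         wilcoxon = wilcoxon_signed_rank(a, b)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d)\n", x$label, x$n))
  print(x$icc_consistency)
  print(x$icc_absolute)
  print(x$bland_altman)
  print(x$wilcoxon)
  invisible(x)
}

agreement_report_to_list <- function(x) {
  icc_l <- function(r) {
    list(icc = r$icc, ci_low = r$ci_low, ci_high = r$ci_high,
         f_value = r$f_value, df1 = r$df1, df2 = r$df2,
         p_value = r$p_value, variant = r$variant, n = r$n)
  }
  list(label = x$label, n = x$n,
       icc_consistency = icc_l(x$icc_consistency),
       icc_absolute = icc_l(x$icc_absolute),
       bland_altman = list(bias = x$bland_altman$bias,
                           loa_low = x$bland_altman$loa_low,
                           loa_high = x$bland_altman$loa_high,
                           n = x$bland_altman$n),
       wilcoxon = list(statistic = x$wilcoxon$statistic,
                       n_effective = x$wilcoxon$n_effective,
                       p_value = x$wilcoxon$p_value,
                       method = x$wilcoxon$method))
}
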