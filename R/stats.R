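#' Intraclass correlation ICC(A,1)
#'
#' Single-rater, absolute-agreement intraclass correlation under the two-way
#' mixed-effects model (McGraw & Wong's ICC(A,1)), computed from the two-way
#' ANOVA mean squares, with the F-based 95% confidence interval. Absolute
#' agreement penalises systematic offsets between raters, unlike the
#' consistency form.
#'
#' @param ratings numeric matrix or data frame, subjects in rows, raters in
#'   columns; at least two of each, no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `model` descriptor, `n_subjects`, `n_raters`.
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (!is.numeric(m)) stop_arg("`ratings` must be numeric")
  if (anyNA(m)) stop_arg("`ratings` must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_arg("need at least 2 subjects and 2 raters")

  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_rater <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  msr <- ss_subj / (n - 1)       # between subjects
  msc <- ss_rater / (k - 1)      # between raters
  mse <- ss_err / ((n - 1) * (k - 1))

  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    lo <- hi <- est  # degenerate: perfect agreement
  } else {
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_lo <- stats::qf(1 - alpha / 2, n - 1, v)
    f_hi <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_lo * mse) /
      (f_lo * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_hi * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_hi * msr)
  }
  structure(list(estimate = est, ci_low = lo, ci_high = hi,
                 model = "two-way mixed effects, absolute agreement, single rater",
                 n_subjects = n, n_raters = k, conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%d%% CI: %.3f-%.3f; %s; %d subjects x %d raters)\n",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$model, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Kolmogorov-Smirnov normality gate
#'
#' Returns `TRUE` (treat as normal) iff the test does not reject normality
#' at `alpha`. Because the normal parameters are estimated from the sample,
#' the Lilliefors-corrected statistic is used by default; the uncorrected
#' one-sample KS test against `N(mean(x), sd(x))` is available with
#' `lilliefors = FALSE`. A degenerate (constant) sample is never treated as
#' normal.
#'
#' @param x numeric sample, n >= 5.
#' @param alpha significance level (default 0.05).
#' @param lilliefors use the Lilliefors correction (default `TRUE`).
#' @return logical scalar.
#' @export
ks_normality <- function(x, alpha = 0.05, lilliefors = TRUE) {
  x <- as.numeric(x)
  if (length(x) < 5) stop_arg("need at least 5 observations")
  if (stats::sd(x) == 0) return(FALSE)
  p <- if (lilliefors) {
    nortest::lillie.test(x)$p.value
  } else {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  p >= alpha
}

#' Rank-biserial correlation from a Mann-Whitney U statistic
#'
#' `r = 1 - 2U / (n_a n_b)`, where `U` counts the pairs in which the second
#' group's observation exceeds the first group's (ties counted half), so the
#' result is positive when group a is stochastically larger. Equivalently,
#' it is the difference between the proportion of dominant and dominated
#' pairs.
#'
#' @param u Mann-Whitney U statistic of group b (pairs with b > a).
#' @param n_a,n_b group sizes.
#' @return rank-biserial correlation in `[-1, 1]`.
#' @export
rank_biserial <- function(u, n_a, n_b) {
  if (n_a < 1 || n_b < 1) stop_arg("group sizes must be positive")
  if (u < 0 || u > n_a * n_b) stop_arg("`u` must lie in [0, n_a * n_b]")
  1 - 2 * u / (n_a * n_b)
}

#' Normality-gated two-group comparison
#'
#' Implements the study-style analysis path: both samples are gated with
#' [ks_normality()]; if both pass, an independent two-sample t test (pooled
#' variance) is used and the effect size is Cohen's d on the pooled SD with
#' the 95% CI of the mean difference; otherwise a Mann-Whitney U test is
#' used with the rank-biserial correlation as effect size.
#'
#' @param a,b numeric samples (n >= 2 each; the KS gate needs n >= 5, smaller
#'   samples fall back to the rank test).
#' @param alpha significance level of the normality gate (default 0.05).
#' @param lilliefors passed to [ks_normality()].
#' @return object of class `cpr_comparison`: `test` (`"T_TEST"` or
#'   `"MANN_WHITNEY"`), `statistic`, `p_value`, `effect` (named: `d` or
#'   `rank_biserial`), `mean_diff`/`ci` (t path), and per-group summaries
#'   (mean/SD and median/IQR).
#' @export
compare_groups <- function(a, b, alpha = 0.05, lilliefors = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop_arg("each sample needs n >= 2")
  normal <- length(a) >= 5 && length(b) >= 5 &&
    ks_normality(a, alpha, lilliefors) && ks_normality(b, alpha, lilliefors)

  summaries <- data.frame(
    group = c("a", "b"), n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
    median = c(stats::median(a), stats::median(b)),
    iqr = c(stats::IQR(a), stats::IQR(b)), stringsAsFactors = FALSE)

  if (normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
    res <- list(test = "T_TEST", statistic = unname(tt$statistic),
                p_value = tt$p.value,
                effect = c(d = d),
                mean_diff = mean(a) - mean(b),
                ci = unname(tt$conf.int),
                summaries = summaries)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
    u_a <- unname(wt$statistic)           # pairs with a > b (ties half)
    u_b <- length(a) * length(b) - u_a
    res <- list(test = "MANN_WHITNEY", statistic = u_a,
                p_value = wt$p.value,
                effect = c(rank_biserial = rank_biserial(u_b, length(a), length(b))),
                mean_diff = NA_real_, ci = c(NA_real_, NA_real_),
                summaries = summaries)
  }
  structure(res, class = "cpr_comparison")
}

#' @export
print.cpr_comparison <- function(x, ...) {
  eff <- sprintf("%s = %.3f", names(x$effect), x$effect)
  cat(sprintf("%s: statistic = %.3f, p = %.4g, %s\n",
              x$test, x$statistic, x$p_value, eff))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric p-value; the two-sided p sums the probabilities of
#' all tables no more likely than the observed one (the convention of
#' [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop_arg("`table` must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop_arg("counts must be non-negative integers")
  stats::fisher.test(m)$p.value
}

#' Raw NASA-TLX workload score
#'
#' The unweighted (raw) NASA task-load index: the arithmetic mean of the six
#' subscale ratings (mental, physical and temporal demand, performance,
#' effort, frustration) on their common scale.
#'
#' @param subscales numeric vector of exactly six ratings.
#' @return the raw TLX score.
#' @export
tlx_raw <- function(subscales) {
  if (length(subscales) != 6 || anyNA(subscales))
    stop_arg("`subscales` must be six non-missing ratings")
  mean(subscales)
}

#' Two-group sample size for a standardised mean difference
#'
#' Normal-approximation a priori sample size per group for a two-sided
#' two-group comparison: `ceil(2 (z_{1-alpha/2} + z_{power})^2 / d^2)`.
#'
#' @param d standardised effect size (Cohen's d, positive).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.8).
#' @return required sample size per group (integer, at least 1).
#' @export
sample_size_two_group <- function(d, alpha = 0.05, power = 0.8) {
  if (!is.numeric(d) || d <= 0) stop_arg("`d` must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_arg("alpha and power must lie in (0, 1)")
  n <- 2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / d^2
  max(1L, as.integer(ceiling(n)))
}
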