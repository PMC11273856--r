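#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences gates the test: a paired t-test
#' when the differences look normal (`shapiro_p >= alpha`), otherwise a
#' Wilcoxon signed-rank test (zero differences excluded; exact distribution
#' for up to 25 non-zero pairs, normal approximation beyond). Differences
#' are `condition - baseline`; p-values are two-sided. Missing pairs are
#' dropped (count recorded). If every difference is zero the comparison is
#' flagged degenerate with `p = 1`.
#'
#' @param baseline,condition per-subject paired values.
#' @param alpha normality-gate level (default 0.05).
#' @param parameter optional endpoint name carried into the result.
#' @return a `paired_comparison` list: `parameter`, `n`, `n_dropped`,
#'   `mean_baseline`, `sd_baseline`, `mean_condition`, `sd_condition`,
#'   `mean_diff`, `sd_diff`, `shapiro_p`, `test_used`
#'   (`"t"`/`"wilcoxon"`/`"none"`), `statistic`, `p_value`, `degenerate`.
#' @export
paired_compare <- function(baseline, condition, alpha = 0.05, parameter = NULL) {
  stopifnot(length(baseline) == length(condition), alpha > 0, alpha < 1)
  ok <- is.finite(baseline) & is.finite(condition)
  n_dropped <- sum(!ok)
  baseline <- baseline[ok]; condition <- condition[ok]
  n <- length(baseline)
  if (n < 3) stop("paired_compare needs at least 3 complete pairs")
  d <- condition - baseline
  res <- list(parameter = parameter, n = n, n_dropped = n_dropped,
              mean_baseline = mean(baseline), sd_baseline = stats::sd(baseline),
              mean_condition = mean(condition), sd_condition = stats::sd(condition),
              mean_diff = mean(d), sd_diff = stats::sd(d),
              differences = d)
  if (all(d == 0)) {
    res <- c(res, list(shapiro_p = NA_real_, test_used = "none",
                       statistic = NA_real_, p_value = 1, degenerate = TRUE))
    return(structure(res, class = "paired_comparison"))
  }
  if (stats::sd(d) == 0) {
    # constant non-zero differences: normality is undefined, rank test applies
    wt <- suppressWarnings(stats::wilcox.test(condition, baseline, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    res <- c(res, list(shapiro_p = NA_real_, test_used = "wilcoxon",
                       statistic = unname(wt$statistic), p_value = wt$p.value,
                       degenerate = FALSE))
    return(structure(res, class = "paired_comparison"))
  }
  shapiro_p <- stats::shapiro.test(d)$p.value
  if (shapiro_p >= alpha) {
    tt <- stats::t.test(condition, baseline, paired = TRUE)
    res <- c(res, list(shapiro_p = shapiro_p, test_used = "t",
                       statistic = unname(tt$statistic), p_value = tt$p.value,
                       degenerate = FALSE))
  } else {
    n_nonzero <- sum(d != 0)
    wt <- suppressWarnings(stats::wilcox.test(condition, baseline, paired = TRUE,
                                              exact = n_nonzero <= 25,
                                              correct = TRUE))
    res <- c(res, list(shapiro_p = shapiro_p, test_used = "wilcoxon",
                       statistic = unname(wt$statistic), p_value = wt$p.value,
                       degenerate = FALSE))
  }
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison>%s n=%d: diff %.3f +/- %.3f, %s test, p = %.4g%s\n",
              if (is.null(x$parameter)) "" else paste0(" ", x$parameter),
              x$n, x$mean_diff, x$sd_diff, x$test_used, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Normality-gated correlation
#'
#' Pearson's correlation when both variables pass the Shapiro-Wilk
#' normality gate at `alpha`, Spearman's rank correlation otherwise;
#' two-sided p-value.
#'
#' @param x,y numeric vectors of equal length (n >= 4, non-constant).
#' @param alpha normality-gate level.
#' @return a `correlation_result` list: `method`, `r`, `p`, `normality_p`
#'   (length-2), `n`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("correlate needs at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlate: zero variance in one of the variables")
  np <- c(x = stats::shapiro.test(x)$p.value, y = stats::shapiro.test(y)$p.value)
  method <- if (all(np >= alpha)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  structure(list(method = method, r = unname(ct$estimate), p = ct$p.value,
                 normality_p = np, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s r = %.3f, p = %.4g (n = %d)\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}

#' Bland-Altman repeatability analysis
#'
#' Differences `scan2 - scan1`; limits of agreement are
#' `mean +/- 1.96 * SD` with the sample (n-1) standard deviation.
#'
#' @param scan1,scan2 paired measurements (n >= 2).
#' @return a `bland_altman_result` list: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `means`, `differences`.
#' @export
bland_altman <- function(scan1, scan2) {
  stopifnot(length(scan1) == length(scan2))
  ok <- is.finite(scan1) & is.finite(scan2)
  scan1 <- scan1[ok]; scan2 <- scan2[ok]
  if (length(scan1) < 2) stop("bland_altman needs at least 2 pairs")
  d <- scan2 - scan1
  bland_altman_from_summary(mean(d), stats::sd(d), n = length(d),
                            means = (scan1 + scan2) / 2, differences = d)
}

#' @rdname bland_altman
#' @param mean_diff,sd_diff summary statistics of the paired differences
#'   (summary-input mode, e.g. for reconstructing published limits).
#' @param n number of pairs (optional in summary mode).
#' @param means,differences optional raw values carried into the result.
#' @export
bland_altman_from_summary <- function(mean_diff, sd_diff, n = NA_integer_,
                                      means = NULL, differences = NULL) {
  stopifnot(is.finite(mean_diff), is.finite(sd_diff), sd_diff >= 0)
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = mean_diff - 1.96 * sd_diff,
                 loa_high = mean_diff + 1.96 * sd_diff,
                 n = n, means = means, differences = differences),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> mean diff %.3f +/- %.3f, 95%% LoA (%.3f, %.3f), n = %s\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, format(x$n)))
  invisible(x)
}

#' Two-sided paired t-test from summary statistics
#'
#' For checking published results: `t = mean_diff / (sd_diff / sqrt(n))`
#' with `n - 1` degrees of freedom.
#'
#' @param mean_diff,sd_diff mean and SD of the paired differences.
#' @param n number of pairs.
#' @return list `statistic`, `df`, `p_value`.
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n) {
  stopifnot(n >= 2, sd_diff > 0)
  tstat <- mean_diff / (sd_diff / sqrt(n))
  list(statistic = tstat, df = n - 1,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 1))
}
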