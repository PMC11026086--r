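#' Normality screen
#'
#' Shapiro-Wilk test with a fixed 0.05 screening level, used to decide
#' between parametric and rank-based association measures. Constant input
#' is flagged degenerate and treated as non-normal rather than erroring.
#'
#' @param values Numeric vector, 4 to 5000 observations.
#' @param alpha Screening level. Default 0.05.
#' @return List with `statistic`, `p_value`, `normal`, `degenerate`, `n`.
#' @export
normality_screen <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) stop("normality screen needs at least 4 values", call. = FALSE)
  if (n > 5000L) stop("normality screen supports at most 5000 values", call. = FALSE)
  if (diff(range(values)) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, normal = FALSE,
                degenerate = TRUE, n = n))
  }
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       normal = sw$p.value > alpha, degenerate = FALSE, n = n)
}

# rank correlation with average ranks for ties; the core statistic behind
# spearman_with_ci(), kept separate so it is testable on tiny inputs
spearman_rho <- function(x, y) {
  cor(rank(x), rank(y))
}

#' Spearman correlation with confidence interval
#'
#' Rank correlation (average ranks for ties) between paired digital and
#' analog stable pressures, with a confidence interval from the Fisher z
#' transform using the Bonett-Wright standard error
#' \eqn{\sqrt{(1 + \rho^2/2)/(n - 3)}}, back-transformed to the correlation
#' scale. A percentile bootstrap interval is available as an alternative.
#' The p-value is the usual rank-correlation test (asymptotic when ties are
#' present).
#'
#' @param digital,analog Paired numeric vectors, n >= 4, no missing values.
#' @param alpha Two-sided interval level complement. Default 0.05 (95% CI).
#' @param method `"fisher"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`. Default 2000.
#' @param label Optional cell label used in error messages.
#' @return List of class `spearman_result`: `rho`, `ci_low`, `ci_high`, `n`,
#'   `p_value`, `method`.
#' @export
spearman_with_ci <- function(digital, analog, alpha = 0.05,
                             method = c("fisher", "bootstrap"),
                             n_boot = 2000L, label = NULL) {
  method <- match.arg(method)
  where <- if (is.null(label)) "" else sprintf(" in cell %s", label)
  if (length(digital) != length(analog)) {
    stop(sprintf("digital and analog must be paired one-to-one%s", where), call. = FALSE)
  }
  keep <- complete.cases(digital, analog)
  if (!all(keep)) stop(sprintf("missing pairs are not allowed%s", where), call. = FALSE)
  n <- length(digital)
  if (n < 4L) stop(sprintf("need at least 4 pairs%s (got %d)", where, n), call. = FALSE)
  if (diff(range(digital)) == 0 || diff(range(analog)) == 0) {
    stop(sprintf("zero rank variance%s: a variable is constant", where), call. = FALSE)
  }
  rho <- spearman_rho(digital, analog)
  p <- suppressWarnings(
    cor.test(digital, analog, method = "spearman", exact = FALSE)$p.value
  )
  if (method == "fisher") {
    if (1 - abs(rho) < 1e-12) {
      ci <- c(rho, rho)
    } else {
      z <- atanh(rho)
      se <- sqrt((1 + rho^2 / 2) / (n - 3))
      ci <- tanh(z + c(-1, 1) * qnorm(1 - alpha / 2) * se)
    }
  } else {
    stat <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (diff(range(digital[i])) == 0 || diff(range(analog[i])) == 0) {
        return(NA_real_)
      }
      cor(rank(digital[i]), rank(analog[i]))
    }, numeric(1))
    ci <- unname(stats::quantile(stat, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  structure(
    list(rho = rho, ci_low = min(ci[1], rho), ci_high = max(ci[2], rho),
         n = n, p_value = p, method = method),
    class = "spearman_result"
  )
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, 95%% CI [%.3f, %.3f], n = %d, p = %.3g (%s CI)\n",
              x$rho, x$ci_low, x$ci_high, x$n, x$p_value, x$method))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Method-comparison statistics on paired digital and analog stable
#' pressures: differences d = digital - analog, bias = mean(d), limits of
#' agreement bias +/- 1.96 sd(d) (sample SD), the count of differences
#' outside the limits, and a proportional-bias check from the straight-line
#' fit of d against the pair means.
#'
#' @param digital,analog Paired numeric vectors, n >= 4.
#' @return List of class `bland_altman_result`: `bias_mmHg`, `sd_diff_mmHg`,
#'   `loa_low`, `loa_high`, `n`, `n_outside_loa`, `proportional_bias_slope`,
#'   `proportional_bias_p`, plus `differences` and `means` for plotting.
#' @examples
#' ba <- bland_altman(c(50, 52, 48, 51), c(49, 52, 49, 50))
#' ba
#' @export
bland_altman <- function(digital, analog) {
  if (length(digital) != length(analog)) {
    stop("digital and analog must be paired one-to-one", call. = FALSE)
  }
  keep <- complete.cases(digital, analog)
  if (!all(keep)) stop("missing pairs are not allowed", call. = FALSE)
  n <- length(digital)
  if (n < 4L) stop(sprintf("need at least 4 pairs (got %d)", n), call. = FALSE)
  d <- digital - analog
  m <- (digital + analog) / 2
  bias <- mean(d)
  s <- sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  slope <- NA_real_
  slope_p <- NA_real_
  if (diff(range(m)) > 0 && s > 0) {
    fit <- lm(d ~ m)
    sm <- summary(fit)$coefficients
    slope <- sm["m", "Estimate"]
    slope_p <- sm["m", "Pr(>|t|)"]
  }
  structure(
    list(bias_mmHg = bias, sd_diff_mmHg = s, loa_low = loa[1], loa_high = loa[2],
         n = n, n_outside_loa = sum(d < loa[1] | d > loa[2]),
         proportional_bias_slope = slope, proportional_bias_p = slope_p,
         differences = d, means = m),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f mmHg, SD %.3f, LoA [%.3f, %.3f], n = %d (%d outside LoA)\n",
    x$bias_mmHg, x$sd_diff_mmHg, x$loa_low, x$loa_high, x$n, x$n_outside_loa
  ))
  if (is.finite(x$proportional_bias_slope)) {
    cat(sprintf("  proportional bias slope %.4f (p = %.3g)\n",
                x$proportional_bias_slope, x$proportional_bias_p))
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x A `bland_altman_result`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman_result <- function(x, main = "Bland-Altman", ...) {
  plot(x$means, x$differences,
       xlab = "Mean of digital and analog (mmHg)",
       ylab = "Digital - analog (mmHg)", main = main, ...)
  abline(h = x$bias_mmHg, lty = 1)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Sample size for detecting a difference between two correlations
#'
#' Fisher z approximation for the number of participants needed to detect
#' that a true correlation `rho_h1` differs from a null value `rho_h0`:
#' \deqn{n = \lceil ((z_{1-\alpha^*} + z_{power}) / (\mathrm{atanh}(\rho_1) -
#'   \mathrm{atanh}(\rho_0)))^2 + 3 \rceil}
#' where \eqn{\alpha^* = \alpha} for a one-tailed test and \eqn{\alpha/2}
#' for two-tailed. With `rho_h1 = 0.9`, `rho_h0 = 0.7`, power 0.80 and
#' one-tailed alpha 0.05 this gives 20 participants.
#'
#' @param rho_h1 Correlation under the alternative.
#' @param rho_h0 Correlation under the null; must satisfy
#'   `-1 < rho_h0 < rho_h1 < 1`.
#' @param power Target power in (0, 1). Default 0.80.
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @param tails `"one"` (default) or `"two"`.
#' @return Integer sample size.
#' @examples
#' required_sample_size(0.9, 0.7)            # 20
#' required_sample_size(0.9, 0.7, tails = "two")  # 25
#' @export
required_sample_size <- function(rho_h1, rho_h0, power = 0.80, alpha = 0.05,
                                 tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (!(power > 0 && power < 1)) stop("'power' must be in (0, 1)", call. = FALSE)
  if (!(-1 < rho_h0 && rho_h0 < rho_h1 && rho_h1 < 1)) {
    stop("need -1 < rho_h0 < rho_h1 < 1 (zero effect is not testable)", call. = FALSE)
  }
  z_a <- qnorm(1 - if (tails == "one") alpha else alpha / 2)
  z_b <- qnorm(power)
  effect <- atanh(rho_h1) - atanh(rho_h0)
  as.integer(ceiling(((z_a + z_b) / effect)^2 + 3))
}
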