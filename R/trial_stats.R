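# Two-proportion trial statistics: Wald intervals, 2x2 chi-square, and the
# normal-approximation sample-size formula used to plan a two-arm responder
# trial (binary endpoint such as ACR20).

#' Wald confidence interval for a single proportion
#'
#' \eqn{p = x/n} with bounds \eqn{p \mp z \sqrt{p(1-p)/n}} clamped to
#' \[0, 1\].
#'
#' @param x Responder count, `0 <= x <= n`.
#' @param n Group size, `>= 1`.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(p, low, high)`.
#' @export
wald_proportion_ci <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    ss_stop("domain", "wald_proportion_ci: need integer counts with 0 <= x <= n, n >= 1")
  }
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(p = p, low = max(p - half, 0), high = min(p + half, 1))
}

#' Risk difference between two groups with Wald confidence interval
#'
#' For a 2x2 outcome table (a responders of n1 in group 1, b of n2 in group
#' 2): \eqn{RD = p_1 - p_2} with bounds
#' \eqn{RD \mp z \sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}}.
#'
#' @param a,n1 Responders and size of group 1.
#' @param b,n2 Responders and size of group 2.
#' @param conf Confidence level (default 0.95).
#' @return List with `p1`, `p2`, `rd`, `ci_low`, `ci_high` (proportions,
#'   unitless; multiply by 100 for percent).
#' @export
risk_difference_ci <- function(a, n1, b, n2, conf = 0.95) {
  if (n1 < 1 || n2 < 1 || a < 0 || a > n1 || b < 0 || b > n2) {
    ss_stop("domain", "risk_difference_ci: need 0 <= a <= n1 and 0 <= b <= n2, sizes >= 1")
  }
  p1 <- a / n1
  p2 <- b / n2
  rd <- p1 - p2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  list(p1 = p1, p2 = p2, rd = rd, ci_low = rd - half, ci_high = rd + half)
}

#' Chi-square test of independence on a 2x2 table
#'
#' On the table \{a, n1-a; b, n2-b\} with N = n1 + n2:
#' \eqn{\chi^2 = N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, one degree of
#' freedom. With `correction = TRUE` the Yates continuity correction
#' \eqn{(|ad - bc| - N/2)^2} replaces the squared term. Default is no
#' correction.
#'
#' @inheritParams risk_difference_ci
#' @param correction Apply the Yates continuity correction (default `FALSE`).
#' @return Named numeric vector `c(statistic, p_value)`.
#' @export
chi_square_2x2 <- function(a, n1, b, n2, correction = FALSE) {
  if (n1 < 1 || n2 < 1 || a < 0 || a > n1 || b < 0 || b > n2) {
    ss_stop("domain", "chi_square_2x2: need 0 <= a <= n1 and 0 <= b <= n2, sizes >= 1")
  }
  cc <- n1 - a
  dd <- n2 - b
  N <- n1 + n2
  margins <- c(a + b, cc + dd, n1, n2)
  if (any(margins == 0)) {
    ss_stop("domain", "chi_square_2x2: a zero margin makes the test undefined")
  }
  num <- a * dd - cc * b
  if (correction) {
    num2 <- (max(abs(num) - N / 2, 0))^2
  } else {
    num2 <- num^2
  }
  stat <- N * num2 / prod(margins)
  c(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Sample size for comparing two proportions
#'
#' Standard normal-approximation formula for a two-sided test of
#' \eqn{H_0: p_1 = p_2} at level \eqn{\alpha} with the given power:
#' \deqn{n = \frac{(z_{\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_\beta\sqrt{p_1 q_1 + p_2 q_2})^2}{\delta^2}}
#' with \eqn{p_2 = p_1 + \delta}, \eqn{\bar p = (p_1 + p_2)/2}, rounded up,
#' then inflated by \eqn{1/(1 - dropout)} and rounded up again.
#'
#' @param p1 Control response proportion, in (0, 1).
#' @param delta Absolute improvement to detect; `p1 + delta` in (0, 1).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.80).
#' @param dropout Anticipated drop-out fraction in \[0, 1) (default 0).
#' @return Required size per group (integer).
#' @export
sample_size_two_proportions <- function(p1, delta, alpha = 0.05, power = 0.80,
                                        dropout = 0) {
  p2 <- p1 + delta
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1 || delta == 0 ||
      alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1 ||
      dropout < 0 || dropout >= 1) {
    ss_stop("domain", "sample_size_two_proportions: infeasible parameters")
  }
  pbar <- (p1 + p2) / 2
  qbar <- 1 - pbar
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- (za * sqrt(2 * pbar * qbar) +
        zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / delta^2
  n <- ceiling(n)
  as.integer(ceiling(n / (1 - dropout)))
}
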