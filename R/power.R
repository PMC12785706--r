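#' Power of a one-sample (paired) t-test
#'
#' Exact noncentral-t power at significance level `alpha` for effect size
#' `d` and sample size `n`: the noncentrality parameter is `d * sqrt(n)`
#' and the test has `n - 1` degrees of freedom.
#'
#' @param n Sample size (>= 2).
#' @param d Population effect size (Cohen's d), > 0.
#' @param alpha Significance level in (0, 1).
#' @param tails 1 or 2.
#' @return Power in (0, 1).
#' @export
t_test_power <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, d > 0, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Minimum sample size for a one-sample t-test
#'
#' Smallest `n` whose noncentral-t power reaches the target.
#'
#' @param d Effect size, > 0.
#' @param alpha Significance level.
#' @param power Target power in (0, 1).
#' @param tails 1 or 2.
#' @param n_floor Smallest admissible sample size (default 2).
#' @return Integer sample size.
#' @examples
#' minimum_sample_size(d = 1, alpha = 0.05, power = 0.9)   # 13
#' minimum_sample_size(d = 0.7, alpha = 0.05, power = 0.9) # 24
#' @export
minimum_sample_size <- function(d, alpha = 0.05, power = 0.9, tails = 2,
                                n_floor = 2) {
  stopifnot(d > 0, power > 0, power < 1)
  for (n in n_floor:1e6) {
    if (t_test_power(n, d, alpha, tails) >= power) return(n)
  }
  stop("target power unreachable at n <= 1e6")
}

#' Critical (sensitivity) effect size for a one-sample t-test
#'
#' The population effect size at which the noncentral-t power of a test
#' with `n` participants equals the target: the smallest effect the design
#' is adequately powered to detect.
#'
#' @param n Sample size (>= 2).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @return Effect size d.
#' @examples
#' critical_effect_size(16, alpha = 0.05, power = 0.9, tails = 1) # ~0.767
#' @export
critical_effect_size <- function(n, alpha = 0.05, power = 0.9, tails = 2) {
  stopifnot(n >= 2, power > 0, power < 1)
  f <- function(d) t_test_power(n, d, alpha, tails) - power
  if (f(100) < 0) stop("no root in (0, 100)")
  stats::uniroot(f, c(1e-8, 100), tol = 1e-10)$root
}
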