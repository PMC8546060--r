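#' Coefficient of variation
#'
#' `CV = sd / |mean|`, the replicate-variability metric used throughout
#' contractile-assay comparisons.
#'
#' @param mean group mean (nonzero).
#' @param sd group standard deviation (>= 0).
#' @return The CV (dimensionless).
#' @examples
#' coefficient_of_variation(0.54, 0.07)  # ~0.13
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(mean == 0)) stop_mbk("CV undefined for zero mean")
  if (any(sd < 0)) stop_mbk("sd must be >= 0")
  sd / abs(mean)
}

#' Percent reduction of a variability (or any) metric
#'
#' `100 (1 - value / reference)`, rounded to the nearest integer for
#' reporting (`round = FALSE` returns the exact value).
#'
#' @param reference baseline value (> 0).
#' @param value comparison value.
#' @param round round to the nearest integer percent?
#' @return Percent reduction.
#' @examples
#' percent_reduction(1.58, 0.21)  # 87
#' @export
percent_reduction <- function(reference, value, round = TRUE) {
  if (any(reference <= 0)) stop_mbk("reference must be positive")
  out <- 100 * (1 - value / reference)
  if (round) base::round(out) else out
}

#' Fold ratio
#'
#' @param a numerator.
#' @param b denominator (> 0).
#' @return `a / b`.
#' @examples
#' fold_ratio(55, 0.5)  # 110
#' @export
fold_ratio <- function(a, b) {
  if (any(b <= 0)) stop_mbk("denominator must be positive")
  a / b
}

#' Two-group sample size from a relative difference and a CV
#'
#' Normal-approximation two-sample formula
#' \deqn{n = 2\,(z_{1-\alpha/2} + z_{1-\beta})^2 (CV/\delta)^2}
#' per group, for detecting a relative difference `delta_rel` between two
#' independent groups whose within-group SD is `CV` times the mean.
#' Rounding is nearest-integer by default (`"ceiling"` for conservative
#' planning); `t_correction = TRUE` iterates with t quantiles
#' (`df = 2n - 2`) instead of normal quantiles.
#'
#' @param cv coefficient of variation (> 0).
#' @param delta_rel relative difference to detect (> 0), e.g. 0.20.
#' @param alpha two-sided type I error rate.
#' @param power desired power `1 - beta`.
#' @param rounding `"nearest"` or `"ceiling"`.
#' @param t_correction use t quantiles iteratively?
#' @return Integer n per group (at least 2).
#' @examples
#' two_group_sample_size(cv = 0.21, delta_rel = 0.20)  # 23
#' @export
two_group_sample_size <- function(cv, delta_rel, alpha = 0.05, power = 0.9,
                                  rounding = c("nearest", "ceiling"),
                                  t_correction = FALSE) {
  rounding <- match.arg(rounding)
  if (cv <= 0) stop_mbk("cv must be positive")
  if (delta_rel <= 0) stop_mbk("delta_rel must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_mbk("alpha and power must lie in (0, 1)")
  rnd <- if (rounding == "nearest") base::round else ceiling
  n_exact <- 2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * (cv / delta_rel)^2
  n <- max(2L, as.integer(rnd(n_exact)))
  if (t_correction) {
    for (it in 1:50) {
      df <- max(2L, 2L * n - 2L)
      n_new <- max(2L, as.integer(rnd(
        2 * (qt(1 - alpha / 2, df) + qt(power, df))^2 * (cv / delta_rel)^2)))
      if (n_new == n) break
      n <- n_new
    }
  }
  n
}

#' Power-analysis specification
#'
#' Bundles the inputs and result of [two_group_sample_size()].
#'
#' @inheritParams two_group_sample_size
#' @return List of class `power_spec` with the inputs and `n_per_group`.
#' @export
power_spec <- function(cv, delta_rel, alpha = 0.05, power = 0.9,
                       rounding = "nearest", t_correction = FALSE) {
  n <- two_group_sample_size(cv, delta_rel, alpha, power, rounding,
                             t_correction)
  structure(list(alpha = alpha, power = power, delta_rel = delta_rel,
                 cv = cv, rounding = rounding, t_correction = t_correction,
                 n_per_group = n),
            class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf(
    "<power_spec> detect %.0f%% difference at CV %.2f (alpha %.2f, power %.2f): n = %d per group\n",
    100 * x$delta_rel, x$cv, x$alpha, x$power, x$n_per_group))
  invisible(x)
}
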