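#' @title Simulation performance measures
#' @description
#' The standard Monte Carlo performance measures of a simulation study: bias,
#' empirical standard error, mean squared error, confidence-interval coverage
#' and null-rejection rate (Type I error under a zero true effect, power
#' otherwise), together with their Monte Carlo standard errors. All measures
#' are computed over the converged repetitions only; the missing-fit count is
#' reported alongside.
#' @name performance
NULL

#' Bias of a set of estimates
#'
#' Mean difference between the repetition estimates and the predefined true
#' effect.
#'
#' @param estimates numeric vector of converged estimates.
#' @param true_x the predefined true effect.
#' @return `mean(estimates) - true_x`.
#' @export
bias <- function(estimates, true_x) {
  if (!length(estimates)) stop("no estimates: bias is undefined", call. = FALSE)
  mean(estimates) - true_x
}

#' Empirical standard error
#'
#' Sample standard deviation (n - 1 divisor) of the estimates across
#' repetitions.
#'
#' @inheritParams bias
#' @return The empirical SE.
#' @export
empirical_se <- function(estimates) {
  if (length(estimates) < 2L)
    stop("need at least 2 estimates for the empirical SE", call. = FALSE)
  stats::sd(estimates)
}

#' Mean squared error
#'
#' Mean squared deviation of the estimates from the true effect (1/n
#' divisor); equals squared bias plus the 1/n-divisor variance.
#'
#' @inheritParams bias
#' @return The MSE.
#' @export
mse <- function(estimates, true_x) {
  if (!length(estimates)) stop("no estimates: MSE is undefined", call. = FALSE)
  mean((estimates - true_x)^2)
}

#' Confidence-interval coverage
#'
#' Fraction of repetitions whose (closed) confidence interval contains the
#' true effect.
#'
#' @param ci_lows,ci_upps numeric vectors of interval bounds from converged
#'   fits.
#' @inheritParams bias
#' @return Coverage in \[0, 1\].
#' @export
coverage <- function(ci_lows, ci_upps, true_x) {
  if (length(ci_lows) != length(ci_upps))
    stop("ci_lows and ci_upps must have equal length", call. = FALSE)
  if (!length(ci_lows)) stop("no intervals: coverage is undefined", call. = FALSE)
  mean(ci_lows <= true_x & true_x <= ci_upps)
}

#' Null-rejection rate
#'
#' Fraction of repetitions with `p <= alpha` (inclusive): the Type I error
#' when the true effect is zero, the power otherwise.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha significance level.
#' @return Rejection rate in \[0, 1\].
#' @export
rejection_rate <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("no p-values: rate is undefined", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  mean(p_values <= alpha)
}

#' Monte Carlo standard errors of the performance measures
#'
#' @param emp_se empirical SE of the estimates.
#' @param coverage_value coverage in \[0, 1\].
#' @param rejection_value rejection rate in \[0, 1\].
#' @param n_valid number of converged repetitions (>= 2).
#' @return Named list `mcse_bias`, `mcse_emp_se`, `mcse_coverage`,
#'   `mcse_rejection`.
#' @examples
#' monte_carlo_ses(2.6, 0.95, 0.05, 5000)$mcse_coverage  # ~0.00308
#' @export
monte_carlo_ses <- function(emp_se, coverage_value, rejection_value,
                            n_valid) {
  if (n_valid < 2L) stop("need n_valid >= 2", call. = FALSE)
  list(
    mcse_bias = emp_se / sqrt(n_valid),
    mcse_emp_se = emp_se / sqrt(2 * (n_valid - 1)),
    mcse_coverage = sqrt(coverage_value * (1 - coverage_value) / n_valid),
    mcse_rejection = sqrt(rejection_value * (1 - rejection_value) / n_valid)
  )
}

#' Summarise one scenario-by-method batch of fits
#'
#' Collapses the converged fits of one method in one scenario into a single
#' performance row. Non-converged fits are excluded listwise and counted in
#' `n_missing`.
#'
#' @param fits data.frame of per-rep fit rows with columns `estimate`, `se`,
#'   `ci_low`, `ci_upp`, `p_value`, `converged` (as produced by
#'   [run_scenario()]), all for a single method.
#' @param true_x predefined true effect of the scenario.
#' @param alpha significance level used for the rejection rate.
#' @param scenario_id,method identifiers copied into the row.
#' @return One-row data.frame with the performance measures and their Monte
#'   Carlo SEs.
#' @export
summarise_performance <- function(fits, true_x, alpha = 0.05,
                                  scenario_id = NA_character_,
                                  method = NA_character_) {
  ok <- which(fits$converged)
  n_valid <- length(ok)
  n_missing <- nrow(fits) - n_valid
  row <- data.frame(
    scenario_id = scenario_id, method = method,
    n_valid = n_valid, n_missing = n_missing,
    mean_estimate = NA_real_, bias = NA_real_, emp_se = NA_real_,
    mse = NA_real_, coverage = NA_real_, rejection_rate = NA_real_,
    mcse_bias = NA_real_, mcse_emp_se = NA_real_,
    mcse_coverage = NA_real_, mcse_rejection = NA_real_,
    stringsAsFactors = FALSE
  )
  if (n_valid == 0L) return(row)
  est <- fits$estimate[ok]
  row$mean_estimate <- mean(est)
  row$bias <- bias(est, true_x)
  row$mse <- mse(est, true_x)
  row$coverage <- coverage(fits$ci_low[ok], fits$ci_upp[ok], true_x)
  row$rejection_rate <- rejection_rate(fits$p_value[ok], alpha)
  if (n_valid >= 2L) {
    row$emp_se <- empirical_se(est)
    m <- monte_carlo_ses(row$emp_se, row$coverage, row$rejection_rate,
                         n_valid)
    row$mcse_bias <- m$mcse_bias
    row$mcse_emp_se <- m$mcse_emp_se
    row$mcse_coverage <- m$mcse_coverage
    row$mcse_rejection <- m$mcse_rejection
  }
  row
}
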