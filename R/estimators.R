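#' @title Treatment-effect estimators for one simulated trial
#' @description
#' Three unadjusted estimators of the arm effect on a discretised PRO score,
#' sharing a common inference contract: a point estimate of the treatment
#' coefficient, its standard error, a two-sided confidence interval and
#' p-value, and a convergence flag. Non-converged fits carry `NA` results and
#' count toward a scenario's missing-fit tally.
#' @name estimators
NULL

fit_result <- function(method, estimate = NA_real_, se = NA_real_,
                       ci_low = NA_real_, ci_upp = NA_real_,
                       p_value = NA_real_, converged = FALSE, aux = NULL) {
  structure(
    list(method = method, estimate = estimate, se = se, ci_low = ci_low,
         ci_upp = ci_upp, p_value = p_value, converged = converged,
         aux = aux),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$method, if (!x$converged) " (not converged)",
      "\n", sep = "")
  if (x$converged)
    cat(sprintf("  estimate %.4f (se %.4f), 95%%-type CI [%.4f, %.4f], p = %.4g\n",
                x$estimate, x$se, x$ci_low, x$ci_upp, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.fit_result <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_upp = x$ci_upp, p_value = x$p_value,
             converged = x$converged, stringsAsFactors = FALSE)
}

arm_split <- function(trial) {
  stopifnot(inherits(trial, "trial_dataset"))
  list(y0 = trial$observed[trial$arm == 0L],
       y1 = trial$observed[trial$arm == 1L])
}

#' Multiple linear regression fit (difference in means)
#'
#' Ordinary least squares of the observed score on an intercept and the arm
#' indicator. For this saturated two-group design the coefficient is the
#' difference in arm means and its standard error is the pooled-variance
#' two-sample formula; inference uses the t distribution with n - 2 degrees
#' of freedom.
#'
#' @param trial a [generate_trial()] `trial_dataset`.
#' @param alpha two-sided significance level (default 0.05).
#' @return A `fit_result`.
#' @export
fit_mlr <- function(trial, alpha = 0.05) {
  ys <- arm_split(trial)
  n0 <- length(ys$y0); n1 <- length(ys$y1)
  if (n0 < 2L || n1 < 2L) return(fit_result("MLR"))
  est <- mean(ys$y1) - mean(ys$y0)
  df <- n0 + n1 - 2L
  s2p <- (sum((ys$y0 - mean(ys$y0))^2) + sum((ys$y1 - mean(ys$y1))^2)) / df
  se <- sqrt(s2p * (1 / n0 + 1 / n1))
  if (!is.finite(se) || se <= 0) return(fit_result("MLR"))
  tstat <- est / se
  q <- stats::qt(1 - alpha / 2, df)
  fit_result("MLR", estimate = est, se = se,
             ci_low = est - q * se, ci_upp = est + q * se,
             p_value = 2 * stats::pt(-abs(tstat), df), converged = TRUE)
}

# Collapse a trial to unique (arm, value) cells with counts and censoring
# status; the Tobit likelihood is then O(k) per evaluation instead of O(n).
tobit_cells <- function(trial, lower, upper) {
  key <- paste(trial$arm, trial$observed)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  arm <- vapply(parts, function(p) as.numeric(p[1]), 0)
  y <- vapply(parts, function(p) as.numeric(p[2]), 0)
  w <- as.numeric(tab)
  status <- ifelse(y <= lower, -1L, ifelse(y >= upper, 1L, 0L))
  list(arm = arm, y = y, w = w, status = status)
}

tobit_loglik_cells <- function(par, cells, lower, upper) {
  b0 <- par[1]; b1 <- par[2]; logs <- par[3]
  if (!all(is.finite(par))) return(-Inf)
  s <- exp(logs)
  eta <- b0 + b1 * cells$arm
  ll <- numeric(length(eta))
  ex <- cells$status == 0L
  lc <- cells$status == -1L
  rc <- cells$status == 1L
  if (any(ex))
    ll[ex] <- stats::dnorm((cells$y[ex] - eta[ex]) / s, log = TRUE) - logs
  if (any(lc))
    ll[lc] <- stats::pnorm((lower - eta[lc]) / s, log.p = TRUE)
  if (any(rc))
    ll[rc] <- stats::pnorm((eta[rc] - upper) / s, log.p = TRUE)
  val <- sum(cells$w * ll)
  if (is.nan(val)) -Inf else val
}

tobit_score_cells <- function(par, cells, lower, upper) {
  b0 <- par[1]; b1 <- par[2]; logs <- par[3]
  s <- exp(logs)
  eta <- b0 + b1 * cells$arm
  d_eta <- numeric(length(eta))
  d_logs <- numeric(length(eta))
  ex <- cells$status == 0L
  lc <- cells$status == -1L
  rc <- cells$status == 1L
  if (any(ex)) {
    z <- (cells$y[ex] - eta[ex]) / s
    d_eta[ex] <- z / s
    d_logs[ex] <- z^2 - 1
  }
  if (any(lc)) {
    zl <- (lower - eta[lc]) / s
    # inverse Mills ratio on the log scale for numerical stability
    lam <- exp(stats::dnorm(zl, log = TRUE) - stats::pnorm(zl, log.p = TRUE))
    d_eta[lc] <- -lam / s
    d_logs[lc] <- -lam * zl
  }
  if (any(rc)) {
    zr <- (eta[rc] - upper) / s
    lam <- exp(stats::dnorm(zr, log = TRUE) - stats::pnorm(zr, log.p = TRUE))
    d_eta[rc] <- lam / s
    d_logs[rc] <- -lam * zr
  }
  c(sum(cells$w * d_eta),
    sum(cells$w * d_eta * cells$arm),
    sum(cells$w * d_logs))
}

#' Two-sided censored-Normal (Tobit) log-likelihood
#'
#' Log-likelihood of a latent-Normal linear model `Y* = b0 + b1 * arm + e`
#' observed only within `[lower, upper]`: scores strictly inside the bounds
#' contribute exact Normal density terms, scores at the bounds contribute
#' Normal tail probabilities. Interior discrete scores are treated as exact
#' (uncensored) observations; censoring status is assigned by exact equality
#' with a bound.
#'
#' @param beta0,beta1 intercept and treatment coefficient (latent scale).
#' @param log_sigma log of the latent residual SD.
#' @param trial a `trial_dataset`.
#' @param lower,upper censoring bounds (defaults 0 and 100).
#' @return The log-likelihood; non-finite (never an error) for non-finite
#'   parameters.
#' @export
tobit_loglik <- function(beta0, beta1, log_sigma, trial, lower = 0,
                         upper = 100) {
  cells <- tobit_cells(trial, lower, upper)
  tobit_loglik_cells(c(beta0, beta1, log_sigma), cells, lower, upper)
}

#' Tobit maximum-likelihood fit
#'
#' Maximises [tobit_loglik()] over `(beta0, beta1, log sigma)` by BFGS with
#' the analytic score, starting from the OLS fit. The treatment-effect
#' estimate is the latent-scale mean difference `beta1`; standard errors come
#' from the inverse observed information (negative Hessian at the optimum),
#' with Wald intervals and p-values on Normal quantiles.
#'
#' @inheritParams fit_mlr
#' @param lower,upper censoring bounds (defaults 0 and 100).
#' @return A `fit_result`; `converged = FALSE` on optimiser failure,
#'   non-positive-definite information, or an arm with no uncensored spread.
#' @export
fit_tobit <- function(trial, lower = 0, upper = 100, alpha = 0.05) {
  ys <- arm_split(trial)
  n0 <- length(ys$y0); n1 <- length(ys$y1)
  if (n0 < 1L || n1 < 1L) return(fit_result("TOBIT"))
  y <- trial$observed
  if (all(y <= lower) || all(y >= upper)) return(fit_result("TOBIT"))

  b0 <- mean(ys$y0)
  b1 <- mean(ys$y1) - b0
  resid <- y - (b0 + b1 * trial$arm)
  s0 <- sqrt(mean(resid^2))
  if (!is.finite(s0) || s0 <= 0) return(fit_result("TOBIT"))

  cells <- tobit_cells(trial, lower, upper)
  negll <- function(p) -tobit_loglik_cells(p, cells, lower, upper)
  neggr <- function(p) -tobit_score_cells(p, cells, lower, upper)

  opt <- tryCatch(
    stats::optim(c(b0, b1, log(s0)), fn = negll, gr = neggr,
                 method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value))
    return(fit_result("TOBIT"))

  hess <- tryCatch(
    stats::optimHess(opt$par, fn = negll, gr = neggr),
    error = function(e) NULL
  )
  if (is.null(hess)) return(fit_result("TOBIT"))
  cov <- tryCatch(chol2inv(chol(hess)), error = function(e) NULL)
  if (is.null(cov) || !all(is.finite(diag(cov))) || any(diag(cov) <= 0))
    return(fit_result("TOBIT"))

  est <- opt$par[2]
  se <- sqrt(cov[2, 2])
  z <- stats::qnorm(1 - alpha / 2)
  fit_result("TOBIT", estimate = est, se = se,
             ci_low = est - z * se, ci_upp = est + z * se,
             p_value = 2 * stats::pnorm(-abs(est / se)), converged = TRUE,
             aux = list(sigma = exp(opt$par[3]), loglik = -opt$value,
                        counts = opt$counts))
}

# Hall-Sheather bandwidth for the median, on the quantile-probability scale.
hall_sheather_h <- function(n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  h <- n^(-1 / 3) * z^(2 / 3) *
    (1.5 * stats::dnorm(0)^2)^(1 / 3) # tau = 0.5 term of the HS constant
  min(h, 0.49)
}

#' Median (least-absolute-deviations) regression fit
#'
#' Minimises the sum of absolute residuals of the observed score on an
#' intercept and the arm indicator. For this two-cell design the conditional
#' medians are the within-arm sample medians (midpoint convention for even
#' arm sizes), and the treatment effect is their difference. Standard errors
#' use the asymptotic sparsity method: an Epanechnikov kernel estimate of the
#' residual density at zero with a Hall-Sheather bandwidth (rescaled by
#' `min(sd, IQR/1.349)` of the residuals), giving
#' `Var(b1) = 0.25 / f(0)^2 * (1/n0 + 1/n1)`; inference is t-based with
#' n - 2 degrees of freedom.
#'
#' Fits where the residual scale or the density estimate at zero degenerates
#' (for example, every residual zero) are flagged `converged = FALSE` and
#' recorded as missing.
#'
#' @inheritParams fit_mlr
#' @return A `fit_result`.
#' @export
fit_median <- function(trial, alpha = 0.05) {
  ys <- arm_split(trial)
  n0 <- length(ys$y0); n1 <- length(ys$y1)
  if (n0 < 2L || n1 < 2L) return(fit_result("MEDIAN"))
  m0 <- stats::median(ys$y0)
  m1 <- stats::median(ys$y1)
  est <- m1 - m0

  resid <- c(ys$y0 - m0, ys$y1 - m1)
  n <- n0 + n1
  scale <- min(stats::sd(resid), stats::IQR(resid) / 1.349)
  if (!is.finite(scale) || scale <= 0) return(fit_result("MEDIAN"))
  h <- hall_sheather_h(n, alpha)
  band <- (stats::qnorm(0.5 + h) - stats::qnorm(0.5 - h)) * scale
  if (!is.finite(band) || band <= 0) return(fit_result("MEDIAN"))
  u <- resid / band
  f0 <- mean(0.75 * (1 - u^2) * (abs(u) <= 1)) / band
  if (!is.finite(f0) || f0 <= 0) return(fit_result("MEDIAN"))

  se <- sqrt(0.25 / f0^2 * (1 / n0 + 1 / n1))
  df <- n - 2L
  tstat <- est / se
  q <- stats::qt(1 - alpha / 2, df)
  fit_result("MEDIAN", estimate = est, se = se,
             ci_low = est - q * se, ci_upp = est + q * se,
             p_value = 2 * stats::pt(-abs(tstat), df), converged = TRUE,
             aux = list(f0 = f0, bandwidth = band))
}

method_registry <- function() {
  list(
    MLR = function(trial, alpha) fit_mlr(trial, alpha),
    TOBIT = function(trial, alpha) fit_tobit(trial, alpha = alpha),
    MEDIAN = function(trial, alpha) fit_median(trial, alpha)
  )
}

normalise_methods <- function(methods) {
  m <- toupper(methods)
  valid <- names(method_registry())
  bad <- setdiff(m, valid)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "), call. = FALSE)
  if (!length(m)) stop("at least one method is required", call. = FALSE)
  m
}

#' Fit a set of estimators to one trial
#'
#' @param trial a `trial_dataset`.
#' @param methods character subset of `c("MLR", "TOBIT", "MEDIAN")`
#'   (case-insensitive).
#' @param alpha two-sided significance level.
#' @return Named list of `fit_result`s.
#' @export
fit_methods <- function(trial, methods = c("MLR", "TOBIT", "MEDIAN"),
                        alpha = 0.05) {
  methods <- normalise_methods(methods)
  reg <- method_registry()
  stats::setNames(lapply(methods, function(m) reg[[m]](trial, alpha)),
                  methods)
}
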