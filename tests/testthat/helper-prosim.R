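# Shared test utilities: hand-built trials, brute-force oracles, numeric
# differentiation.

# Build a trial_dataset directly from observed arm vectors (latent set equal
# to observed; adequate for estimator-level tests).
manual_trial <- function(y0, y1, scenario_id = "manual") {
  y <- c(y0, y1)
  structure(
    list(arm = rep(c(0L, 1L), c(length(y0), length(y1))),
         latent = y, clamped = pmin(pmax(y, 0), 100), observed = y,
         rep_index = 1L, scenario_id = scenario_id),
    class = "trial_dataset"
  )
}

# Brute-force LAD oracle for the intercept + arm design: enumerate all
# candidate vertex solutions (b0 an observed control value, b0 + b1 an
# observed treatment value) and return the minimising effect estimate.
lad_brute_force <- function(y0, y1) {
  best <- Inf; best_b1 <- NA_real_
  for (c0 in unique(y0)) for (c1 in unique(y1)) {
    obj <- sum(abs(y0 - c0)) + sum(abs(y1 - c1))
    if (obj < best - 1e-12) {
      best <- obj
      best_b1 <- c1 - c0
    }
  }
  best_b1
}

# Central finite-difference gradient of f at x.
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# Independent two-pass standard deviation (n - 1 divisor).
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
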