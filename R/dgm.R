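#' Define one simulation scenario
#'
#' A scenario is one cell of the factorial simulation design: a latent
#' Normal(mu, sigma^2) control-arm distribution, a location-shift treatment
#' effect `effect_x`, a score grid, a total sample size `n` split equally
#' between the two arms, a repetition count and a significance level.
#'
#' @param mu latent mean, score points (default 50).
#' @param sigma latent standard deviation, score points (default 22).
#' @param effect_x latent treatment effect added to every treatment-arm draw,
#'   score points.
#' @param n total number of subjects; must be even (n/2 per arm).
#' @param grid a [make_grid()] `score_grid`, or a built-in grid label.
#' @param nsim number of simulation repetitions (default 5000).
#' @param alpha two-sided significance level (default 0.05).
#' @param seed root RNG seed for the scenario's random streams.
#' @param scenario_id text identifier; autogenerated if `NULL`.
#'
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec(effect_x = 22, n = 400, grid = "RE4", nsim = 10, seed = 1)
#' @export
scenario_spec <- function(mu = 50, sigma = 22, effect_x = 0, n = 100,
                          grid = make_grid(10), nsim = 5000, alpha = 0.05,
                          seed = 1L, scenario_id = NULL) {
  if (is.character(grid)) grid <- grid_by_label(grid)
  stopifnot(inherits(grid, "score_grid"))
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (!is.finite(n) || n < 2 || n %% 2 != 0)
    stop("`n` must be an even integer >= 2 (balanced arms)", call. = FALSE)
  if (!is.finite(nsim) || nsim < 1) stop("`nsim` must be >= 1", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (is.null(scenario_id))
    scenario_id <- sprintf("x%g_%s_n%d", effect_x, grid$label, as.integer(n))
  structure(
    list(mu = mu, sigma = sigma, effect_x = effect_x, n = as.integer(n),
         grid = grid, nsim = as.integer(nsim), alpha = alpha,
         seed = as.integer(seed), scenario_id = scenario_id),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$scenario_id, "\n", sep = "")
  cat(sprintf("  latent Normal(%g, %g^2), effect %g, n = %d (%d/arm)\n",
              x$mu, x$sigma, x$effect_x, x$n, x$n %/% 2))
  cat(sprintf("  grid %s (k = %d), nsim = %d, alpha = %g, seed = %d\n",
              x$grid$label, x$grid$k, x$nsim, x$alpha, x$seed))
  invisible(x)
}

# Deterministic per-(seed, n, rep) substream key. Chained Lehmer-style hash
# modulo 2^31 - 1; exact in double arithmetic (products stay below 2^53).
# Within the design space (n <= ~30000, rep <= ~30000) distinct (n, rep)
# pairs cannot collide because 69069 * dn +/- drep never wraps the modulus.
stream_seed <- function(root_seed, n, rep_index) {
  m <- 2147483647
  s <- root_seed %% m
  for (key in c(n, rep_index)) {
    s <- (s * 69069 + (key %% m) + 1) %% m
  }
  as.integer(s)
}

#' Generate the latent scores of one simulated trial
#'
#' Draws `n/2` latent control scores from Normal(mu, sigma^2) and `n/2`
#' treatment scores from the same distribution shifted by `effect_x`. The
#' pre-shift draws depend only on `(seed, n, rep_index)` -- never on the
#' effect size or the grid -- so the identical base sample is reused across
#' all effect sizes and grids (common random numbers).
#'
#' @param spec a [scenario_spec()].
#' @param rep_index repetition number (1-based).
#' @return A list with numeric vectors `control` and `treatment`, each of
#'   length `n/2`.
#' @export
generate_latent <- function(spec, rep_index = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$n %/% 2L
  # local RNG state: the draw must not disturb (or depend on) the caller's
  # global stream
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(stream_seed(spec$seed, spec$n, rep_index))
  z <- stats::rnorm(spec$n)
  list(
    control = spec$mu + spec$sigma * z[seq_len(m)],
    treatment = spec$mu + spec$sigma * z[m + seq_len(m)] + spec$effect_x
  )
}

#' Generate one complete simulated two-arm trial
#'
#' Assembles one repetition of the data-generating mechanism: latent Normal
#' draws per arm (see [generate_latent()]), clamping to \[0, 100\], and
#' discretisation onto the scenario's score grid. Deterministic given
#' `(seed, rep_index, n, mu, sigma, effect_x, grid)`; changing only the grid
#' changes `observed` but not `latent`.
#'
#' @param spec a [scenario_spec()].
#' @param rep_index repetition number (1-based).
#' @return An object of class `trial_dataset`: a list with vectors `arm`
#'   (0 = control, 1 = treatment), `latent`, `clamped`, `observed`, plus
#'   `rep_index` and `scenario_id`.
#' @export
generate_trial <- function(spec, rep_index = 1L) {
  lat <- generate_latent(spec, rep_index)
  latent <- c(lat$control, lat$treatment)
  arm <- rep(c(0L, 1L), each = spec$n %/% 2L)
  clamped <- clamp_scores(latent)
  observed <- clamp_and_discretise(latent, spec$grid)
  structure(
    list(arm = arm, latent = latent, clamped = clamped, observed = observed,
         rep_index = as.integer(rep_index), scenario_id = spec$scenario_id),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- length(x$arm)
  cat("<trial_dataset> ", x$scenario_id, " rep ", x$rep_index,
      ": n = ", n, "\n", sep = "")
  cat(sprintf("  observed means: control %.2f, treatment %.2f\n",
              mean(x$observed[x$arm == 0L]), mean(x$observed[x$arm == 1L])))
  invisible(x)
}

#' Convert a trial to a tidy data frame
#'
#' @param x a [generate_trial()] `trial_dataset`.
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return data.frame with columns scenario_id, rep, subject, arm, latent,
#'   clamped, observed.
#' @export
as.data.frame.trial_dataset <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(
    scenario_id = x$scenario_id,
    rep = x$rep_index,
    subject = seq_along(x$arm),
    arm = x$arm,
    latent = x$latent,
    clamped = x$clamped,
    observed = x$observed,
    stringsAsFactors = FALSE
  )
}

#' Write simulated trials to a tidy CSV
#'
#' @param trials a `trial_dataset` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  if (inherits(trials, "trial_dataset")) trials <- list(trials)
  df <- do.call(rbind, lapply(trials, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
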