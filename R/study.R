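#' Configure the full factorial simulation study
#'
#' The default configuration is the full study design: five location-shift
#' treatment effects (0, 4.4, 11, 17.6 and 22 points, i.e. Cohen's d of 0,
#' 0.2, 0.5, 0.8 and 1.0 at sigma = 22), three score grids (RE4, BP10,
#' MH26), six total sample sizes (100 to 1600), 5000 repetitions per
#' scenario, and all three estimators at alpha = 0.05.
#'
#' @param root_seed integer root seed; every random stream of the study is
#'   derived deterministically from it.
#' @param dgm_effects numeric vector of latent treatment effects.
#' @param grids character vector of built-in grid labels.
#' @param sample_sizes even integer total sample sizes.
#' @param nsim repetitions per scenario.
#' @param alpha two-sided significance level.
#' @param methods subset of `c("MLR", "TOBIT", "MEDIAN")`.
#' @param mu,sigma latent Normal mean and SD (score points).
#' @param output_dir optional directory for CSV/JSON outputs.
#' @param keep_fits keep (and write) the per-repetition fit table; needed for
#'   estimate histograms and scatterplots.
#' @return An object of class `study_config`.
#' @export
study_config <- function(root_seed = 1L,
                         dgm_effects = c(0, 4.4, 11, 17.6, 22),
                         grids = c("RE4", "BP10", "MH26"),
                         sample_sizes = c(100L, 200L, 400L, 800L, 1200L, 1600L),
                         nsim = 5000L, alpha = 0.05,
                         methods = c("MLR", "TOBIT", "MEDIAN"),
                         mu = 50, sigma = 22,
                         output_dir = NULL, keep_fits = TRUE) {
  dedupe <- function(x, what) {
    if (anyDuplicated(x)) {
      warning("duplicate ", what, " values removed", call. = FALSE)
      x <- unique(x)
    }
    x
  }
  if (!length(dgm_effects) || !length(grids) || !length(sample_sizes))
    stop("effect, grid and sample-size lists must be non-empty", call. = FALSE)
  dgm_effects <- dedupe(dgm_effects, "effect")
  grids <- dedupe(grids, "grid")
  sample_sizes <- dedupe(sample_sizes, "sample size")
  for (g in grids) grid_by_label(g)  # validate labels early
  if (any(sample_sizes %% 2 != 0))
    stop("all sample sizes must be even (balanced arms)", call. = FALSE)
  methods <- normalise_methods(methods)
  structure(
    list(root_seed = as.integer(root_seed), dgm_effects = dgm_effects,
         grids = grids, sample_sizes = as.integer(sample_sizes),
         nsim = as.integer(nsim), alpha = alpha, methods = methods,
         mu = mu, sigma = sigma, output_dir = output_dir,
         keep_fits = isTRUE(keep_fits)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  effects:", paste(x$dgm_effects, collapse = ", "), "\n")
  cat("  grids:  ", paste(x$grids, collapse = ", "), "\n")
  cat("  n:      ", paste(x$sample_sizes, collapse = ", "), "\n")
  cat(sprintf("  nsim = %d, alpha = %g, seed = %d, methods: %s\n",
              x$nsim, x$alpha, x$root_seed,
              paste(x$methods, collapse = ", ")))
  invisible(x)
}

#' Expand a study configuration into scenario specifications
#'
#' Deterministic ordering: effect (slowest), then grid, then sample size.
#' The default configuration yields 90 scenarios (5 x 3 x 6).
#'
#' @param config a [study_config()].
#' @return List of [scenario_spec()] objects with stable `scenario_id`s.
#' @export
expand_scenarios <- function(config) {
  stopifnot(inherits(config, "study_config"))
  out <- list()
  for (x in config$dgm_effects)
    for (g in config$grids)
      for (n in config$sample_sizes)
        out[[length(out) + 1L]] <- scenario_spec(
          mu = config$mu, sigma = config$sigma, effect_x = x, n = n,
          grid = g, nsim = config$nsim, alpha = config$alpha,
          seed = config$root_seed
        )
  out
}

#' Run one simulation scenario
#'
#' Generates `nsim` trials from the scenario's data-generating mechanism,
#' fits each requested estimator to every trial, and summarises each method
#' into a performance row. Estimator failures are recorded as non-converged
#' repetitions, never raised.
#'
#' @param spec a [scenario_spec()].
#' @param methods subset of `c("MLR", "TOBIT", "MEDIAN")`.
#' @param keep_fits return the per-repetition fit table (default TRUE).
#' @return List with elements `fits` (data.frame of per-rep results, or
#'   `NULL` when `keep_fits = FALSE`) and `performance` (one row per
#'   method).
#' @export
run_scenario <- function(spec, methods = c("MLR", "TOBIT", "MEDIAN"),
                         keep_fits = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  methods <- normalise_methods(methods)
  nm <- length(methods)
  nrow_total <- spec$nsim * nm
  cols <- list(
    rep = integer(nrow_total), method = character(nrow_total),
    estimate = numeric(nrow_total), se = numeric(nrow_total),
    ci_low = numeric(nrow_total), ci_upp = numeric(nrow_total),
    p_value = numeric(nrow_total), converged = logical(nrow_total)
  )
  reg <- method_registry()
  at <- 0L
  for (r in seq_len(spec$nsim)) {
    trial <- generate_trial(spec, r)
    for (m in methods) {
      fit <- tryCatch(reg[[m]](trial, spec$alpha),
                      error = function(e) fit_result(m))
      at <- at + 1L
      cols$rep[at] <- r
      cols$method[at] <- m
      cols$estimate[at] <- fit$estimate
      cols$se[at] <- fit$se
      cols$ci_low[at] <- fit$ci_low
      cols$ci_upp[at] <- fit$ci_upp
      cols$p_value[at] <- fit$p_value
      cols$converged[at] <- fit$converged
    }
  }
  fits <- data.frame(scenario_id = spec$scenario_id, cols,
                     stringsAsFactors = FALSE)
  perf <- do.call(rbind, lapply(methods, function(m) {
    summarise_performance(fits[fits$method == m, , drop = FALSE],
                          true_x = spec$effect_x, alpha = spec$alpha,
                          scenario_id = spec$scenario_id, method = m)
  }))
  perf$effect_x <- spec$effect_x
  perf$grid <- spec$grid$label
  perf$k <- spec$grid$k
  perf$n <- spec$n
  perf$nsim <- spec$nsim
  list(fits = if (keep_fits) fits else NULL, performance = perf)
}

#' Run the full simulation study
#'
#' Runs every scenario of the configuration sequentially (each scenario's
#' random streams are keyed by the root seed, so results are independent of
#' execution order), aggregates tidy per-repetition and performance tables,
#' and optionally writes `estimates.csv`, `performance.csv`, `manifest.json`
#' and `run.log` to `config$output_dir`.
#'
#' @param config a [study_config()].
#' @param verbose print per-scenario progress lines.
#' @return List with `performance` (data.frame), `estimates` (data.frame or
#'   `NULL`), and `config`.
#' @export
run_study <- function(config, verbose = interactive()) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$output_dir
  log_lines <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    probe <- file.path(out_dir, ".write_probe")
    ok <- tryCatch({ writeLines("", probe); unlink(probe); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("output_dir is not writable: ", out_dir, call. = FALSE)
  }
  scenarios <- expand_scenarios(config)
  perf_list <- vector("list", length(scenarios))
  fit_list <- if (config$keep_fits) vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sp <- scenarios[[i]]
    res <- run_scenario(sp, config$methods, keep_fits = config$keep_fits)
    perf_list[[i]] <- res$performance
    if (config$keep_fits) fit_list[[i]] <- res$fits
    msg <- sprintf("[%d/%d] %s: valid fits %s", i, length(scenarios),
                   sp$scenario_id,
                   paste(sprintf("%s=%d", res$performance$method,
                                 res$performance$n_valid), collapse = " "))
    log_lines <- c(log_lines, msg)
    if (verbose) message(msg)
  }
  performance <- do.call(rbind, perf_list)
  estimates <- if (config$keep_fits) do.call(rbind, fit_list)
  if (!is.null(out_dir)) {
    utils::write.csv(performance, file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    if (!is.null(estimates))
      utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                       row.names = FALSE)
    manifest <- list(
      config = config[c("root_seed", "dgm_effects", "grids", "sample_sizes",
                        "nsim", "alpha", "methods", "mu", "sigma")],
      n_scenarios = length(scenarios),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("prosim")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(performance = performance, estimates = estimates, config = config)
}
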