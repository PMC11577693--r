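#' @title Tables and figures from tidy study results
#' @description
#' Pure functions of the tidy `performance` and `estimates` tables produced
#' by [run_study()]: the wide mean-estimate table, estimate histograms,
#' estimate-vs-SE scatterplots, method-vs-method scatterplots, and
#' performance line plots against sample size with the conventional
#' reference lines (0 for bias/MSE, 0.95 for coverage, alpha for the Type I
#' error). Display rounding never feeds back into the stored results.
#' @name reporting
NULL

parse_scenario_id <- function(id) {
  m <- regmatches(id, regexec("^x([0-9.]+)_([A-Za-z0-9]+)_n([0-9]+)$", id))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("unparseable scenario_id: ", id[bad][1], call. = FALSE)
  data.frame(
    effect_x = as.numeric(vapply(m, `[`, "", 2L)),
    grid = vapply(m, `[`, "", 3L),
    n = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

dgm_number <- function(effect_x) {
  lev <- sort(unique(effect_x))
  match(effect_x, lev)
}

#' Wide table of mean treatment-effect estimates
#'
#' One row per (sample size, DGM), one column per (method, grid), each cell
#' the mean converged estimate rounded to 3 decimal places for display.
#' Missing scenario/method combinations appear as `NA` rather than being
#' silently dropped.
#'
#' @param performance the performance data.frame from [run_study()] /
#'   [run_scenario()].
#' @param digits display rounding (default 3).
#' @return data.frame with columns `n`, `dgm`, `effect_x`, then
#'   `<method>_<grid>` mean-estimate columns.
#' @export
make_table5 <- function(performance, digits = 3) {
  stopifnot(all(c("scenario_id", "method", "mean_estimate") %in%
                  names(performance)))
  meta <- parse_scenario_id(performance$scenario_id)
  d <- cbind(meta, performance[c("method", "mean_estimate")])
  d$dgm <- dgm_number(d$effect_x)
  rows <- unique(d[order(d$dgm, d$n), c("n", "dgm", "effect_x")])
  methods <- unique(d$method)
  grids <- unique(d$grid)
  out <- rows
  for (g in grids) for (m in methods) {
    col <- paste(m, g, sep = "_")
    sel <- d[d$method == m & d$grid == g, ]
    idx <- match(paste(rows$n, rows$dgm), paste(sel$n, sel$dgm))
    out[[col]] <- round(sel$mean_estimate[idx], digits)
  }
  rownames(out) <- NULL
  out
}

measure_registry <- function() {
  list(
    bias = list(col = "bias", ref = 0, lab = "Bias"),
    emp_se = list(col = "emp_se", ref = NA_real_, lab = "Empirical SE"),
    mse = list(col = "mse", ref = 0, lab = "MSE"),
    coverage = list(col = "coverage", ref = 0.95, lab = "Coverage of 95% CI"),
    rejection = list(col = "rejection_rate", ref = 0.05,
                     lab = "Rejection rate (Type I error / power)")
  )
}

#' Line plot of a performance measure against sample size
#'
#' One panel per (grid x DGM), the x axis the total sample size, one line
#' per method, with the measure's dashed reference line (0 for bias and MSE,
#' 0.95 for coverage; for the rejection rate the nominal alpha = 0.05 line
#' is drawn in the null-effect panels, where the rate is the Type I error).
#'
#' @param performance performance data.frame from [run_study()].
#' @param measure one of `"bias"`, `"emp_se"`, `"mse"`, `"coverage"`,
#'   `"rejection"`.
#' @return A ggplot object.
#' @export
plot_performance <- function(performance, measure = "bias") {
  reg <- measure_registry()
  if (!measure %in% names(reg))
    stop("unknown measure '", measure, "'; valid: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  if (!nrow(performance)) stop("empty performance table", call. = FALSE)
  spec <- reg[[measure]]
  meta <- parse_scenario_id(performance$scenario_id)
  d <- cbind(meta, performance[setdiff(names(performance), names(meta))])
  d$dgm <- factor(paste("DGM", dgm_number(d$effect_x)))
  d$grid <- factor(d$grid, levels = unique(d$grid))
  d$value <- d[[spec$col]]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$value,
                                       colour = .data$method,
                                       group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$dgm),
                        cols = ggplot2::vars(.data$grid)) +
    ggplot2::labs(x = "Total sample size", y = spec$lab, colour = "Method") +
    ggplot2::theme_bw()
  if (measure == "rejection") {
    nullpan <- unique(d[d$effect_x == 0, c("dgm", "grid")])
    if (nrow(nullpan)) {
      nullpan$ref <- 0.05
      p <- p + ggplot2::geom_hline(data = nullpan,
                                   ggplot2::aes(yintercept = .data$ref),
                                   linetype = "dashed")
    }
  } else if (is.finite(spec$ref)) {
    p <- p + ggplot2::geom_hline(yintercept = spec$ref, linetype = "dashed")
  }
  p
}

#' Histograms of per-repetition estimates
#'
#' One panel per (grid x DGM), faceting the per-rep estimate distribution of
#' one or more methods; the dashed vertical line marks the true effect and
#' the dotted line zero. On coarse grids the median-regression estimates
#' concentrate near multiples of the score gap.
#'
#' @param estimates per-rep estimates data.frame from [run_study()] (needs
#'   `keep_fits = TRUE`).
#' @param methods methods to include.
#' @param bins histogram bin count.
#' @return A ggplot object.
#' @export
plot_estimates_hist <- function(estimates, methods = NULL, bins = 60) {
  d <- estimates[estimates$converged, , drop = FALSE]
  if (!is.null(methods)) d <- d[d$method %in% normalise_methods(methods), ]
  if (!nrow(d)) stop("no converged estimates to plot", call. = FALSE)
  meta <- parse_scenario_id(d$scenario_id)
  d <- cbind(meta, d[setdiff(names(d), names(meta))])
  d$dgm <- factor(paste("DGM", dgm_number(d$effect_x)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$effect_x),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$dgm),
                        cols = ggplot2::vars(.data$grid, .data$method)) +
    ggplot2::labs(x = "Estimated treatment effect", y = "Repetitions") +
    ggplot2::theme_bw()
}

#' Scatterplot of estimates against their standard errors
#'
#' @inheritParams plot_estimates_hist
#' @return A ggplot object.
#' @export
plot_est_vs_se <- function(estimates, methods = NULL) {
  d <- estimates[estimates$converged, , drop = FALSE]
  if (!is.null(methods)) d <- d[d$method %in% normalise_methods(methods), ]
  if (!nrow(d)) stop("no converged estimates to plot", call. = FALSE)
  meta <- parse_scenario_id(d$scenario_id)
  d <- cbind(meta, d[setdiff(names(d), names(meta))])
  d$dgm <- factor(paste("DGM", dgm_number(d$effect_x)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$se)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$dgm),
                        cols = ggplot2::vars(.data$grid, .data$method)) +
    ggplot2::labs(x = "Estimated treatment effect", y = "Standard error") +
    ggplot2::theme_bw()
}

#' Scatterplot of one method's estimates against another's
#'
#' Repetition-matched comparison (same scenario, same simulated trial) of
#' two estimators, as used to show Tobit's agreement with MLR and the
#' striped pattern of median regression.
#'
#' @inheritParams plot_estimates_hist
#' @param x_method,y_method the two methods to compare.
#' @return A ggplot object.
#' @export
plot_method_vs_method <- function(estimates, x_method = "MLR",
                                  y_method = "TOBIT") {
  x_method <- normalise_methods(x_method)
  y_method <- normalise_methods(y_method)
  dx <- estimates[estimates$method == x_method & estimates$converged, ]
  dy <- estimates[estimates$method == y_method & estimates$converged, ]
  d <- merge(dx[c("scenario_id", "rep", "estimate")],
             dy[c("scenario_id", "rep", "estimate")],
             by = c("scenario_id", "rep"), suffixes = c("_x", "_y"))
  if (!nrow(d)) stop("no repetition-matched pairs to plot", call. = FALSE)
  meta <- parse_scenario_id(d$scenario_id)
  d <- cbind(meta, d[setdiff(names(d), names(meta))])
  d$dgm <- factor(paste("DGM", dgm_number(d$effect_x)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate_x,
                                  y = .data$estimate_y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$dgm),
                        cols = ggplot2::vars(.data$grid)) +
    ggplot2::labs(x = paste(x_method, "estimate"),
                  y = paste(y_method, "estimate")) +
    ggplot2::theme_bw()
}

#' Write performance line plots to image files
#'
#' Renders [plot_performance()] for each requested measure to
#' deterministically named PNG files.
#'
#' @param performance performance data.frame.
#' @param dir output directory (created if needed).
#' @param measures measures to render (default all).
#' @param width,height device size in inches.
#' @return Character vector of file paths, invisibly.
#' @export
make_performance_plots <- function(performance, dir,
                                   measures = names(measure_registry()),
                                   width = 9, height = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in measures) {
    p <- plot_performance(performance, m)
    path <- file.path(dir, paste0("performance_", m, ".png"))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    paths <- c(paths, path)
  }
  invisible(paths)
}
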