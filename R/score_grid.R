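#' Discrete PRO score grids
#'
#' A `score_grid` describes one bounded discrete patient-reported-outcome
#' scale: the `k` printed score values on the 0--100 scale and the `k - 1`
#' interior bin boundaries used to discretise a continuous score onto them.
#' Intervals are left-open/right-closed, so a continuous value lying exactly
#' on a boundary maps to the *lower* score.
#'
#' Three grids corresponding to SF-36 dimension scales are built in:
#'
#' * `"RE4"` -- role limitation (emotional), k = 4, scores 0, 33.3, 66.6, 100;
#' * `"BP10"` -- bodily pain, k = 10, scores 0, 11.1, ..., 88.9, 100;
#' * `"MH26"` -- mental health, k = 26, scores 0, 4, 8, ..., 96, 100.
#'
#' Note the built-in score values are the published scale values, which are
#' not always arithmetic midpoints (e.g. 55.6 and 66.7 on the 10-level grid).
#' For any other `k`, equally spaced scores `100 * j / (k - 1)` with midpoint
#' boundaries are generated.
#'
#' @param k integer number of score levels (>= 2).
#' @param scores optional numeric vector of `k` strictly increasing score
#'   values with `scores[1] == 0` and `scores[k] == 100`.
#' @param edges optional numeric vector of `k - 1` strictly increasing
#'   interior boundaries; `edges[j]` must lie strictly between `scores[j]`
#'   and `scores[j + 1]`.
#' @param label text identifier for the grid.
#'
#' @return An object of class `score_grid`: a list with elements `k`,
#'   `scores`, `edges` and `label`.
#' @examples
#' make_grid(4)                       # built-in RE-style grid
#' make_grid(2)                       # generic: scores 0/100, edge 50
#' make_grid(5, label = "custom5")    # generic equally spaced grid
#' @export
make_grid <- function(k, scores = NULL, edges = NULL, label = NULL) {
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 2)
    stop("`k` must be a single integer >= 2", call. = FALSE)
  k <- as.integer(k)

  if (is.null(scores) && is.null(edges)) {
    built_in <- builtin_grid_tables()
    key <- as.character(k)
    if (key %in% names(built_in)) {
      g <- built_in[[key]]
      scores <- g$scores
      edges <- g$edges
      if (is.null(label)) label <- g$label
    } else {
      scores <- 100 * (seq_len(k) - 1) / (k - 1)
      edges <- (scores[-k] + scores[-1]) / 2
    }
  } else if (is.null(scores) || is.null(edges)) {
    stop("supply both `scores` and `edges`, or neither", call. = FALSE)
  }
  if (is.null(label)) label <- paste0("G", k)

  validate_grid_parts(k, scores, edges)
  structure(
    list(k = k, scores = as.numeric(scores), edges = as.numeric(edges),
         label = as.character(label)),
    class = "score_grid"
  )
}

# Printed scale values and discretisation boundaries for the three SF-36
# dimension scales (RE: 4 levels, BP: 10 levels, MH: 26 levels).
builtin_grid_tables <- function() {
  list(
    `4` = list(
      label = "RE4",
      scores = c(0, 33.3, 66.6, 100),
      edges = c(16.65, 49.95, 83.25)
    ),
    `10` = list(
      label = "BP10",
      scores = c(0, 11.1, 22.2, 33.3, 44.4, 55.6, 66.7, 77.8, 88.9, 100),
      edges = c(5.55, 16.65, 27.75, 38.85, 49.95, 61.05, 72.15, 83.25, 94.35)
    ),
    `26` = list(
      label = "MH26",
      scores = seq(0, 100, by = 4),
      edges = seq(2, 98, by = 4)
    )
  )
}

#' Look up a built-in grid by label
#'
#' @param label one of `"RE4"`, `"BP10"`, `"MH26"`.
#' @return A [make_grid()] `score_grid`.
#' @export
grid_by_label <- function(label) {
  tabs <- builtin_grid_tables()
  labs <- vapply(tabs, `[[`, "", "label")
  hit <- match(label, labs)
  if (is.na(hit))
    stop("unknown grid label '", label, "'; built-ins: ",
         paste(labs, collapse = ", "), call. = FALSE)
  make_grid(as.integer(names(tabs)[hit]))
}

validate_grid_parts <- function(k, scores, edges) {
  if (length(scores) != k)
    stop("`scores` must have length k = ", k, call. = FALSE)
  if (length(edges) != k - 1)
    stop("`edges` must have length k - 1 = ", k - 1, call. = FALSE)
  if (!all(is.finite(scores)) || !all(is.finite(edges)))
    stop("scores and edges must be finite", call. = FALSE)
  ds <- diff(scores)
  if (any(ds <= 0))
    stop("`scores` not strictly increasing at index ",
         which(ds <= 0)[1], call. = FALSE)
  de <- diff(edges)
  if (length(de) && any(de <= 0))
    stop("`edges` not strictly increasing at index ",
         which(de <= 0)[1], call. = FALSE)
  if (scores[1] != 0 || scores[k] != 100)
    stop("scores must start at 0 and end at 100", call. = FALSE)
  bad <- which(edges <= scores[-k] | edges >= scores[-1])
  if (length(bad))
    stop("edge ", bad[1], " (", edges[bad[1]],
         ") does not lie strictly between scores ", scores[bad[1]],
         " and ", scores[bad[1] + 1], call. = FALSE)
  invisible(TRUE)
}

#' @export
print.score_grid <- function(x, ...) {
  cat("<score_grid> ", x$label, ": k = ", x$k, "\n", sep = "")
  cat("  scores:", paste(x$scores, collapse = ", "), "\n")
  cat("  edges: ", paste(x$edges, collapse = ", "), "\n")
  invisible(x)
}

#' Clamp latent scores to the 0--100 scale
#'
#' @param x numeric vector of latent scores.
#' @return `pmin(pmax(x, 0), 100)`.
#' @export
clamp_scores <- function(x) pmin(pmax(x, 0), 100)

#' Clamp and discretise continuous scores onto a grid
#'
#' Values are first clamped to \[0, 100\], then mapped to the grid score of
#' the left-open/right-closed bin they fall in: a value in
#' `(edges[j-1], edges[j]]` maps to `scores[j]` (with the outer bins extending
#' to plus/minus infinity). A value exactly on a boundary maps to the lower
#' score.
#'
#' @param x numeric vector of continuous scores (any real values).
#' @param grid a [make_grid()] `score_grid`.
#' @return numeric vector of the same length, each element one of
#'   `grid$scores`.
#' @examples
#' g10 <- make_grid(10)
#' clamp_and_discretise(10.5, g10)   # 11.1
#' clamp_and_discretise(10.5, make_grid(26))  # 12
#' @export
clamp_and_discretise <- function(x, grid) {
  stopifnot(inherits(grid, "score_grid"))
  v <- clamp_scores(x)
  # left.open = TRUE: bin index counts edges strictly below v, so v == edge
  # stays in the lower bin, matching the ( , ] convention.
  idx <- findInterval(v, grid$edges, left.open = TRUE) + 1L
  grid$scores[idx]
}
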