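# Markov quantity model: the class transition matrix is estimated by
# cross-tabulating two dated maps cell by cell, and future class quantities
# are obtained by pushing the current composition through the matrix
# (one step = one observed inter-map interval).

#' Estimate a transition model from two dated maps
#'
#' Cross-tabulates origin (t) against destination (t+1) over cells valid at
#' both dates: counts[i, j] = cells with code i at t and j at t+1. Row i of
#' the probability matrix is counts[i, ] / rowSums; rows with no origin
#' cells are identity rows.
#'
#' @param grid_t0,grid_t1 Congruent [lulc_grid]s sharing a legend.
#' @param step_years Nominal interval length (metadata only).
#' @return Object of class `transition_model`: `classes`, `counts`, `P`,
#'   `step_years`.
#' @export
estimate_transition <- function(grid_t0, grid_t1, step_years = 10) {
  stopifnot(is_lulc_grid(grid_t0), is_lulc_grid(grid_t1))
  check_congruent(grid_t0, grid_t1)
  classes <- sort(as.integer(union(names(grid_t0$legend),
                                   names(grid_t1$legend))))
  ok <- !is.na(grid_t0$codes) & !is.na(grid_t1$codes)
  if (!any(ok)) stop("no valid overlapping cells")
  counts <- table(factor(grid_t0$codes[ok], levels = classes),
                  factor(grid_t1$codes[ok], levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(classes, classes))
  P <- counts / pmax(rowSums(counts), 1)
  empty <- rowSums(counts) == 0L
  P[empty, ] <- 0
  diag(P)[empty] <- 1
  structure(list(classes = classes, counts = counts, P = P,
                 step_years = step_years),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model: %d classes, %g-year step>\n",
              length(x$classes), x$step_years))
  print(round(x$P, 4))
  invisible(x)
}

#' Project class quantities forward through the transition matrix
#'
#' One step corresponds to one observed interval. Quantities may be areas or
#' cell counts; the total is conserved exactly because every row of P sums
#' to one: out_j = sum_i in_i * P[i, j].
#'
#' @param model A `transition_model`.
#' @param areas_t Non-negative vector over `model$classes`.
#' @param steps Number of steps (>= 1).
#' @return Numeric vector named by class.
#' @export
project_class_areas <- function(model, areas_t, steps = 1L) {
  stopifnot(inherits(model, "transition_model"), steps >= 1L)
  if (length(areas_t) != length(model$classes))
    stop("areas_t must have one entry per class")
  if (any(areas_t < 0)) stop("negative input area")
  a <- as.numeric(areas_t)
  for (s in seq_len(steps)) a <- as.numeric(crossprod(model$P, a))
  stats::setNames(a, model$classes)
}

#' Integer CA quantity targets from projected areas
#'
#' Largest-remainder rounding of the one-step projection of the grid's cell
#' counts, so targets are integers summing exactly to the valid-cell count.
#'
#' @param model A `transition_model`.
#' @param grid The [lulc_grid] being advanced.
#' @return Integer vector named by class.
#' @export
markov_targets <- function(model, grid) {
  n0 <- class_counts(grid)
  if (length(n0) != length(model$classes))
    stop("grid legend does not match transition model classes")
  proj <- project_class_areas(model, n0, steps = 1L)
  stats::setNames(largest_remainder(proj, total = sum(n0)), model$classes)
}
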