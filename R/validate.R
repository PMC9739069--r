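# Agreement between a simulated and a reference categorical map:
# cell-by-cell cross-tabulation and the chance-corrected Kappa statistic,
# with the qualitative banding used for judging simulation quality
# (poor < 0.4 <= general < 0.75 <= very good).

#' Cross-tabulate a reference and a simulated map
#'
#' counts[i, j] = cells coded i in the reference and j in the simulation;
#' cells that are nodata in either map are excluded.
#'
#' @param reference,simulated Congruent [lulc_grid]s sharing a legend.
#' @return Object of class `confusion_matrix`: `classes`, `counts`.
#' @export
cross_tabulate <- function(reference, simulated) {
  stopifnot(is_lulc_grid(reference), is_lulc_grid(simulated))
  check_congruent(reference, simulated)
  classes <- sort(as.integer(union(names(reference$legend),
                                   names(simulated$legend))))
  ok <- !is.na(reference$codes) & !is.na(simulated$codes)
  counts <- table(factor(reference$codes[ok], levels = classes),
                  factor(simulated$codes[ok], levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(classes, classes))
  structure(list(classes = classes, counts = counts),
            class = "confusion_matrix")
}

#' Kappa coefficient of a confusion matrix
#'
#' Observed agreement P0 is the diagonal fraction; chance agreement Pc is
#' the sum of products of row and column marginal proportions (Cohen's
#' definition); Kappa = (P0 - Pc) / (1 - Pc). If both maps are constant and
#' identical (Pc = 1), Kappa is defined as 1 with a warning.
#'
#' @param cm A `confusion_matrix` (or a plain square count matrix).
#' @return List: `P0`, `Pc`, `kappa`, `band` (one of `"poor"`, `"general"`,
#'   `"very good"`).
#' @export
kappa_statistic <- function(cm) {
  counts <- if (inherits(cm, "confusion_matrix")) cm$counts else as.matrix(cm)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  total <- sum(counts)
  if (total <= 0) stop("empty confusion matrix")
  P0 <- sum(diag(counts)) / total
  Pc <- sum((rowSums(counts) / total) * (colSums(counts) / total))
  if (Pc >= 1 - 1e-15) {
    warning("both maps constant and identical; Kappa defined as 1")
    kap <- 1
  } else {
    kap <- (P0 - Pc) / (1 - Pc)
  }
  band <- if (kap < 0.4 - 1e-9) "poor"
          else if (kap < 0.75 - 1e-9) "general"
          else "very good"
  list(P0 = P0, Pc = Pc, kappa = kap, band = band)
}
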