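# Landscape-pattern metrics on categorical rasters, following the
# conventions of the standard raster landscape-analysis tools: patches are
# connected components of like-coded cells (default 8-neighbour), while
# like-adjacency counting for the aggregation index is 4-neighbour and
# single-count. Class-scale indices: NP, MPS, LPI, PSCV, DIVISION, AI;
# landscape scale adds SHDI.

#' Delineate patches (connected components of like-coded cells)
#'
#' Uses iterative minimum-label propagation with pointer doubling; patch ids
#' are assigned in row-major order of each patch's first cell, so labelling
#' is deterministic. Nodata cells get label 0.
#'
#' @param grid A [lulc_grid].
#' @param connectivity 4 (rook) or 8 (queen, default).
#' @return Object of class `patch_labelling`: `labels` (integer matrix,
#'   0 = nodata), `patches` (data.frame: `patch`, `class`, `cells`,
#'   `area_ha`), `connectivity`.
#' @export
label_patches <- function(grid, connectivity = 8L) {
  stopifnot(is_lulc_grid(grid))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  codes <- grid$codes
  nr <- nrow(codes); nc <- ncol(codes); n <- nr * nc
  valid <- !is.na(codes)
  lab <- seq_len(n)                      # column-major linear index
  lab[!valid] <- NA_integer_
  labm <- matrix(lab, nr, nc)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  repeat {
    old <- labm
    for (s in shifts) {
      nb_lab <- shift_mat(labm, s[1], s[2], fill = NA)
      nb_code <- shift_mat(codes, s[1], s[2], fill = NA)
      same <- valid & !is.na(nb_code) & nb_code == codes
      labm[same] <- pmin(labm[same], nb_lab[same])
    }
    v <- as.vector(labm)                 # pointer doubling
    for (it in 1:3) {
      w <- v
      ok <- !is.na(v)
      w[ok] <- v[v[ok]]
      if (identical(w, v)) break
      v <- w
    }
    labm <- matrix(v, nr, nc)
    if (identical(labm, old)) break
  }
  roots <- as.vector(labm)
  uniq <- sort(unique(roots[!is.na(roots)]))
  # order patches by the row-major position of their first cell
  rowmaj <- (matrix(seq_len(nr), nr, nc) - 1L) * nc +
    matrix(seq_len(nc), nr, nc, byrow = TRUE)
  first_rm <- vapply(uniq, function(r)
    min(rowmaj[which(roots == r)]), numeric(1))
  ord <- uniq[order(first_rm)]
  ids <- integer(n)
  ids[!is.na(roots)] <- match(roots[!is.na(roots)], ord)
  cells <- tabulate(ids[ids > 0L], nbins = length(ord))
  cls <- codes[match(ord, roots)]        # representative cell's code
  cell_ha <- grid$cell_size^2 / 1e4
  structure(list(labels = matrix(ids, nr, nc),
                 patches = data.frame(patch = seq_along(ord), class = cls,
                                      cells = cells,
                                      area_ha = cells * cell_ha),
                 connectivity = as.integer(connectivity)),
            class = "patch_labelling")
}

#' Like-adjacency count of one class (rook, single-count)
#' @noRd
like_adjacencies <- function(codes, class) {
  isk <- !is.na(codes) & codes == class
  sum(isk[-nrow(codes), , drop = FALSE] & isk[-1, , drop = FALSE]) +
    sum(isk[, -ncol(codes), drop = FALSE] & isk[, -1, drop = FALSE])
}

#' Maximum like-adjacency count achievable by A cells (largest-square bound)
#' @noRd
max_like_adjacencies <- function(A) {
  n <- floor(sqrt(A)); m <- A - n^2
  if (m == 0) 2 * n * (n - 1)
  else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
  else 2 * n * (n - 1) + 2 * m - 2
}

#' Class-scale landscape metrics
#'
#' One row per class present: NP (patch count), MPS (mean patch size, ha),
#' LPI (largest patch as % of the whole landscape area), PSCV (100 x
#' population standard deviation of patch areas / MPS), DIVISION
#' (1 - sum over class patches of (a/A)^2), and AI (100 x like
#' adjacencies / largest-square bound; 0 for a single-cell class, whose
#' bound is zero).
#'
#' @param grid A [lulc_grid].
#' @param connectivity Patch connectivity, 4 or 8 (default 8).
#' @param labelling Optional precomputed [label_patches()] result.
#' @return data.frame: `class`, `NP`, `MPS_ha`, `LPI_pct`, `PSCV`,
#'   `DIVISION`, `AI_pct`.
#' @export
class_metrics <- function(grid, connectivity = 8L, labelling = NULL) {
  stopifnot(is_lulc_grid(grid))
  if (is.null(labelling)) labelling <- label_patches(grid, connectivity)
  pat <- labelling$patches
  A <- sum(pat$area_ha)                  # total landscape area
  classes <- sort(unique(pat$class))
  rows <- lapply(classes, function(k) {
    a <- pat$area_ha[pat$class == k]
    np <- length(a)
    mps <- mean(a)
    pscv <- if (mps > 0) 100 * sqrt(mean((a - mps)^2)) / mps else 0
    division <- 1 - sum((a / A)^2)
    cells_k <- sum(pat$cells[pat$class == k])
    g <- like_adjacencies(grid$codes, k)
    gmax <- max_like_adjacencies(cells_k)
    ai <- if (gmax > 0) 100 * g / gmax else 0
    data.frame(class = k, NP = np, MPS_ha = mps,
               LPI_pct = 100 * max(a) / A, PSCV = pscv,
               DIVISION = division, AI_pct = ai)
  })
  do.call(rbind, rows)
}

#' Landscape-scale metrics
#'
#' NP and MPS over all patches, LPI of the single largest patch, PSCV over
#' all patch areas, AI as the class-area-weighted mean of class AIs, and
#' SHDI = -sum P_i ln P_i over class area proportions.
#'
#' @inheritParams class_metrics
#' @return One-row data.frame: `NP`, `MPS_ha`, `LPI_pct`, `PSCV`, `AI_pct`,
#'   `SHDI`.
#' @export
landscape_metrics <- function(grid, connectivity = 8L, labelling = NULL) {
  stopifnot(is_lulc_grid(grid))
  if (is.null(labelling)) labelling <- label_patches(grid, connectivity)
  pat <- labelling$patches
  if (!nrow(pat)) stop("empty landscape")
  A <- sum(pat$area_ha)
  a <- pat$area_ha
  mps <- mean(a)
  cm <- class_metrics(grid, connectivity, labelling)
  p_i <- vapply(cm$class, function(k)
    sum(pat$area_ha[pat$class == k]) / A, numeric(1))
  data.frame(NP = nrow(pat), MPS_ha = mps,
             LPI_pct = 100 * max(a) / A,
             PSCV = if (mps > 0) 100 * sqrt(mean((a - mps)^2)) / mps else 0,
             AI_pct = sum(p_i * cm$AI_pct),
             SHDI = -sum(p_i * log(p_i)))
}

#' Full metrics report (class + landscape scale)
#'
#' @inheritParams class_metrics
#' @return Object of class `metrics_report`: list with `class` and
#'   `landscape` data.frames, `connectivity`, `label`.
#' @export
metrics_report <- function(grid, connectivity = 8L) {
  labelling <- label_patches(grid, connectivity)
  structure(list(class = class_metrics(grid, connectivity, labelling),
                 landscape = landscape_metrics(grid, connectivity, labelling),
                 connectivity = connectivity, label = grid$label),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report '%s' (connectivity %d)>\nLandscape:\n",
              x$label, x$connectivity))
  print(x$landscape, row.names = FALSE)
  cat("Classes:\n")
  print(x$class, row.names = FALSE)
  invisible(x)
}

#' Change in landscape metrics between two dates
#'
#' Absolute and percent change of every landscape-scale index between a
#' first and a last report (percent change relative to the first date).
#'
#' @param first,last `metrics_report` objects.
#' @return data.frame: `index`, `first`, `last`, `change`, `change_pct`.
#' @export
metrics_change <- function(first, last) {
  stopifnot(inherits(first, "metrics_report"),
            inherits(last, "metrics_report"))
  f <- unlist(first$landscape[1, ]); l <- unlist(last$landscape[1, ])
  data.frame(index = names(f), first = unname(f), last = unname(l),
             change = unname(l - f),
             change_pct = unname(ifelse(f != 0, 100 * (l - f) / f, NA)))
}
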