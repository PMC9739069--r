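#' Align driver layers onto a reference grid and optionally standardize
#'
#' Builds a `driver_stack`: a named list of real-valued matrices congruent
#' with a reference land-cover grid. Layers whose dimensions divide the
#' reference evenly are upsampled by nearest neighbour (the convention used
#' for coarser climate and socio-economic rasters); congruent layers pass
#' through unchanged. With `standardize = TRUE`, each layer is z-scored over
#' the reference's valid cells and the centring/scaling constants recorded.
#'
#' @param layers Named list of numeric matrices.
#' @param reference A [lulc_grid] defining shape and valid mask.
#' @param standardize Z-score each layer over valid cells?
#' @return Object of class `driver_stack`: list with `layers`, `standardized`,
#'   `center`, `scale`, `cell_size`.
#' @export
align_and_stack <- function(layers, reference, standardize = FALSE) {
  stopifnot(is_lulc_grid(reference), is.list(layers), length(layers) > 0)
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all driver layers must be named")
  dim_ref <- dim(reference$codes)
  valid <- !is.na(reference$codes)
  out <- vector("list", length(layers)); names(out) <- names(layers)
  center <- scale <- stats::setNames(rep(NA_real_, length(layers)), names(layers))
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m)) stop("layer '", nm, "' is not a matrix")
    if (!identical(dim(m), dim_ref)) {
      if (dim_ref[1] %% nrow(m) != 0 || dim_ref[2] %% ncol(m) != 0)
        stop("layer '", nm, "' cannot be nearest-neighbour resampled to ",
             paste(dim_ref, collapse = "x"))
      m <- resample_nn(m, dim_ref[1], dim_ref[2])
    }
    storage.mode(m) <- "double"
    if (standardize) {
      v <- m[valid]
      mu <- mean(v); sd <- stats::sd(v)
      if (!is.finite(sd) || sd == 0)
        stop("layer '", nm, "' has zero variance; cannot standardize")
      m <- (m - mu) / sd
      center[nm] <- mu; scale[nm] <- sd
    }
    out[[nm]] <- m
  }
  structure(list(layers = out, standardized = standardize,
                 center = center, scale = scale,
                 cell_size = reference$cell_size),
            class = "driver_stack")
}

is_driver_stack <- function(x) inherits(x, "driver_stack")

#' @export
print.driver_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<driver_stack: %d layers, %dx%d%s>\n", length(x$layers),
              d[1], d[2], if (x$standardized) ", standardized" else ""))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Nearest-neighbour upsampling of a matrix to a finer target shape
#'
#' Each target cell takes the value of the source cell whose centre is
#' nearest (target centres mapped proportionally into the source lattice).
#'
#' @param m Numeric matrix.
#' @param nrow_out,ncol_out Target dimensions.
#' @return Matrix of the target shape.
#' @export
resample_nn <- function(m, nrow_out, ncol_out) {
  ri <- pmin(nrow(m), pmax(1L, ceiling((seq_len(nrow_out) - 0.5) *
                                         nrow(m) / nrow_out)))
  ci <- pmin(ncol(m), pmax(1L, ceiling((seq_len(ncol_out) - 0.5) *
                                         ncol(m) / ncol_out)))
  m[ri, ci, drop = FALSE]
}
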