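# Per-class binary logistic suitability models: occurrence of land type k is
# regressed on the driver stack (logit p = b0 + b1 X1 + ... + bn Xn), scored
# by rank-based ROC area, and mapped into per-class probability atlases that
# drive the CA allocation.

#' Stratified sample of cells with driver values
#'
#' Draws up to `n_per_class` cells per class without replacement (classes
#' with fewer cells contribute all their cells, with a warning) and attaches
#' the driver value at each sampled cell. The same table serves every
#' per-class model so that driver subsets are compared on a common sample.
#'
#' @param grid A [lulc_grid].
#' @param drivers A `driver_stack` congruent with `grid`.
#' @param n_per_class Cells sampled per class (default 5000).
#' @param seed Integer seed.
#' @return data.frame: `cell` (1-based column-major index), `code`, one
#'   column per driver.
#' @export
sample_observations <- function(grid, drivers, n_per_class = 5000L,
                                seed = 1L) {
  stopifnot(is_lulc_grid(grid), is_driver_stack(drivers))
  stopifnot(n_per_class >= 30L)
  codes <- grid$codes
  classes <- sort(unique(codes[!is.na(codes)]))
  idx <- withr::with_seed(sub_seed(seed, 30L), {
    unlist(lapply(classes, function(k) {
      cells <- which(!is.na(codes) & codes == k)
      if (length(cells) < n_per_class) {
        warning("class ", k, " has only ", length(cells),
                " cells; sampling all of them")
        cells
      } else sample(cells, n_per_class)
    }))
  })
  out <- data.frame(cell = idx, code = codes[idx])
  for (nm in names(drivers$layers)) out[[nm]] <- drivers$layers[[nm]][idx]
  out
}

#' Fit the occurrence logistic model of one class
#'
#' Maximum-likelihood binary logistic regression of `code == class` on the
#' chosen drivers, with presences balanced against an equal-sized seeded
#' subsample of absences. Aliased (perfectly collinear) drivers get
#' coefficient 0, which leaves predictions unchanged; apparent separation
#' ends in a bounded-iteration estimate with a warning rather than failure.
#'
#' @param obs Observation table from [sample_observations()].
#' @param class Class code to model.
#' @param subset Driver names to use (default: all driver columns).
#' @param balance Balance absences to the presence count?
#' @param seed Seed for the absence subsample.
#' @return List: `class`, `intercept`, `coefficients` (named), `roc`,
#'   `subset`, `converged`, `n`.
#' @export
fit_class_logistic <- function(obs, class, subset = NULL, balance = TRUE,
                               seed = 1L) {
  drv <- setdiff(names(obs), c("cell", "code"))
  if (is.null(subset)) subset <- drv
  bad <- setdiff(subset, drv)
  if (length(bad))
    stop("unknown driver(s) in subset: ", paste(bad, collapse = ", "))
  y <- as.integer(obs$code == class)
  if (length(unique(y)) < 2L)
    stop("degenerate response for class ", class,
         ": needs both presences and absences")
  keep <- seq_len(nrow(obs))
  if (balance) {
    pres <- which(y == 1L); abs_ <- which(y == 0L)
    if (length(abs_) > length(pres)) {
      abs_ <- withr::with_seed(sub_seed(seed, 40L + as.integer(class)),
                               sample(abs_, length(pres)))
    }
    keep <- sort(c(pres, abs_))
  }
  dat <- cbind(data.frame(y = y[keep]), obs[keep, subset, drop = FALSE])
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        warning("class ", class, ": separation suspected; ",
                "bounded-iteration estimates returned", call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0            # aliased under exact collinearity
  scores <- as.vector(cbind(1, as.matrix(dat[, subset, drop = FALSE])) %*% cf)
  list(class = class,
       intercept = unname(cf["(Intercept)"]),
       coefficients = cf[subset],
       roc = roc_area(scores, dat$y),
       subset = subset,
       converged = fit$converged,
       n = nrow(dat))
}

#' Fit suitability models for every class
#'
#' @inheritParams fit_class_logistic
#' @param classes Class codes to fit (default: all present in `obs`).
#' @return Object of class `logistic_model_set`: list of per-class fits.
#' @export
fit_suitability <- function(obs, classes = sort(unique(obs$code)),
                            subset = NULL, seed = 1L) {
  models <- lapply(classes, function(k)
    fit_class_logistic(obs, k, subset = subset, seed = seed))
  names(models) <- as.character(classes)
  structure(models, class = "logistic_model_set")
}

#' @export
print.logistic_model_set <- function(x, ...) {
  cat("<logistic_model_set>\n")
  for (m in x)
    cat(sprintf("  class %s: ROC %.3f (%d drivers, n=%d)\n",
                m$class, m$roc, length(m$coefficients), m$n))
  invisible(x)
}

#' Predict per-class suitability atlases
#'
#' Evaluates p_k(x) = 1 / (1 + exp(-(b0 + sum_j b_j X_j(x)))) for every
#' class over the driver stack. Nodata in `reference` (if given) propagates
#' into the atlases.
#'
#' @param models A `logistic_model_set`.
#' @param drivers `driver_stack` holding every driver a model uses (on the
#'   same scale as at fitting time).
#' @param reference Optional [lulc_grid] supplying a nodata mask.
#' @return Object of class `suitability_atlas`: named list of probability
#'   matrices in `[0, 1]`.
#' @export
predict_suitability <- function(models, drivers, reference = NULL) {
  stopifnot(inherits(models, "logistic_model_set"))
  dims <- dim(drivers$layers[[1]])
  mask <- if (!is.null(reference)) is.na(reference$codes) else NULL
  atlas <- lapply(models, function(m) {
    missing <- setdiff(names(m$coefficients), names(drivers$layers))
    if (length(missing))
      stop("missing driver layer(s): ", paste(missing, collapse = ", "))
    eta <- matrix(m$intercept, dims[1], dims[2])
    for (nm in names(m$coefficients))
      eta <- eta + m$coefficients[[nm]] * drivers$layers[[nm]]
    p <- 1 / (1 + exp(-eta))
    if (!is.null(mask)) p[mask] <- NA_real_
    p
  })
  names(atlas) <- names(models)
  structure(atlas, class = "suitability_atlas")
}

#' Rank-based ROC area
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half; identical to the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), both values present.
#' @return Scalar in `[0, 1]`.
#' @export
roc_area <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both label values must be present")
  r <- rank(scores)             # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Region-wide ROC of a suitability atlas
#'
#' Rank-based ROC of each class's probability surface against the observed
#' occurrence of that class, over every valid cell of the map. This is the
#' map-scale discrimination of the atlas (the training-sample ROC stored in
#' each model depends on the stratified sampling mixture instead).
#'
#' @param atlas A `suitability_atlas`.
#' @param grid The observed [lulc_grid].
#' @return Named numeric vector, one ROC per class present in the grid.
#' @export
atlas_roc <- function(atlas, grid) {
  stopifnot(inherits(atlas, "suitability_atlas"), is_lulc_grid(grid))
  ok <- !is.na(grid$codes)
  classes <- names(atlas)
  out <- vapply(classes, function(k) {
    y <- grid$codes[ok] == as.integer(k)
    if (!any(y) || all(y)) return(NA_real_)
    roc_area(atlas[[k]][ok], y)
  }, numeric(1))
  out
}

#' Compare per-class ROC across driver subsets
#'
#' Fits every class once per subset on a common observation sample and
#' tabulates the ROC areas; with exactly two subsets a difference column
#' (first minus second) is added.
#'
#' @param grid A [lulc_grid].
#' @param drivers Congruent `driver_stack`.
#' @param subsets Named list of driver-name character vectors.
#' @param n_per_class,seed Passed to [sample_observations()].
#' @return data.frame: one row per class, one ROC column per subset.
#' @export
compare_driver_subsets <- function(grid, drivers, subsets,
                                   n_per_class = 5000L, seed = 1L) {
  stopifnot(is.list(subsets), length(subsets) >= 1L)
  if (any(!lengths(subsets))) stop("empty driver subset")
  if (is.null(names(subsets)))
    names(subsets) <- paste0("subset", seq_along(subsets))
  obs <- sample_observations(grid, drivers, n_per_class, seed)
  classes <- sort(unique(obs$code))
  out <- data.frame(class = classes)
  for (nm in names(subsets)) {
    fits <- fit_suitability(obs, classes, subset = subsets[[nm]], seed = seed)
    out[[nm]] <- vapply(fits, function(m) m$roc, numeric(1))
  }
  if (length(subsets) == 2L)
    out$difference <- out[[names(subsets)[1]]] - out[[names(subsets)[2]]]
  out
}
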