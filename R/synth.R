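# Synthetic study-region generator: driver stacks with the four driver
# categories (terrain, climate gradients, accessibility distances, blocky
# county-level socio-economics), an initial six-class map drawn from known
# multinomial-logistic coefficients, and forward transitions governed by a
# known row-stochastic matrix. Everything downstream can then be validated
# against ground truth.

#' Default configuration of the synthetic scenario
#'
#' Composition targets mirror an agro-pastoral mosaic: cultivated ~38%,
#' forest ~11%, grassland ~46%, water ~0.5%, built up ~3%, deserted ~2%.
#' One simulation step represents a decade.
#'
#' @return Named list of generation parameters.
#' @export
scenario_config <- function() {
  list(
    shape = c(256L, 256L),
    cell_size = 500,
    composition = c(`1` = 0.38, `2` = 0.11, `3` = 0.46,
                    `4` = 0.005, `5` = 0.03, `6` = 0.02),
    smooth_passes_elev = 6L,     # low-pass passes for the elevation field
    smooth_half = 3L,            # window half-width of each pass
    elev_scale = 1,              # amplitude of the elevation field
    county_block = 32L,          # side of a "county" in cells
    n_built_points = 5L,         # seeds of the distance-to-built-up layer
    n_road_lines = 4L,           # seeds of the distance-to-road layer
    map_smoothing_passes = 2L,   # 3x3 majority passes on the initial map
    labels = c("2000", "2010", "2020"),
    step_years = 10
  )
}

#' Ground-truth logistic coefficients of the default scenario
#'
#' One row per class over `(Intercept)` plus the eleven driver layers of
#' [generate_drivers()]. Coefficients are on standardized drivers; magnitudes
#' (roughly 0.5-6) are chosen so that each class occupies a clearly separable
#' environmental niche: cultivated land on gentle, warm, accessible terrain;
#' forest on steep, wet uplands; grassland on drier grazing land; water in
#' the lowest basins; built-up next to existing built-up seeds; deserted land
#' where precipitation is lowest. Intercepts here are placeholders; the
#' generator calibrates them to the composition targets.
#'
#' @param driver_names Driver layer names (default: the generator's eleven).
#' @return Numeric matrix, classes 1-6 by (Intercept + drivers).
#' @export
scenario_true_beta <- function(driver_names = scenario_driver_names()) {
  k <- 6L
  b <- matrix(0, k, length(driver_names) + 1L,
              dimnames = list(as.character(1:k),
                              c("(Intercept)", driver_names)))
  set_b <- function(cls, ...) {
    v <- c(...)
    b[cls, names(v)] <<- v
  }
  set_b("1", elevation = -0.6, slope = -1.5, temperature = 1.0,
        precipitation = 1.2, dist_built = -0.8, agri_output = 2.5,
        livestock_density = -1.5)
  set_b("2", elevation = 1.0, slope = 2.2, precipitation = 2.0,
        temperature = -1.0, dist_road = 0.6, livestock_density = -1.5)
  set_b("3", precipitation = -0.8, livestock_density = 2.5, slope = 0.4,
        dist_built = 0.6, elevation = 0.5, agri_output = -1.5)
  set_b("4", elevation = -6.0, slope = -2.0)
  set_b("5", dist_built = -6.0, gdp = 1.0, pop_density = 0.8, slope = -0.8)
  set_b("6", precipitation = -4.0, temperature = 1.2, agri_output = -1.0,
        aspect = 0.3)
  # sharpen every niche relative to the unit-scale sampling noise so class
  # membership is strongly environment-determined
  b[, -1] <- 1.5 * b[, -1]
  b
}

#' Driver layer names of the default synthetic stack
#' @return Character vector of eleven layer names.
#' @export
scenario_driver_names <- function() {
  c("elevation", "slope", "aspect", "precipitation", "temperature",
    "dist_built", "dist_road", "pop_density", "gdp", "agri_output",
    "livestock_density")
}

#' Ground-truth decadal transition matrix of the default scenario
#'
#' Strongly diagonal (a decade changes a minority of cells), with the main
#' observed flows: cultivated <-> grassland exchange, afforestation,
#' built-up expansion, and deserted-land recovery to grassland.
#'
#' @return 6x6 row-stochastic matrix (rows = origin class).
#' @export
scenario_true_P <- function() {
  P <- rbind(
    c(0.930, 0.015, 0.030, 0.001, 0.020, 0.004),
    c(0.020, 0.940, 0.035, 0.001, 0.003, 0.001),
    c(0.045, 0.020, 0.920, 0.001, 0.004, 0.010),
    c(0.002, 0.000, 0.006, 0.990, 0.000, 0.002),
    c(0.010, 0.000, 0.005, 0.000, 0.985, 0.000),
    c(0.008, 0.000, 0.040, 0.002, 0.000, 0.950))
  dimnames(P) <- list(as.character(1:6), as.character(1:6))
  P
}

#' Generate the synthetic driver stack
#'
#' Eleven layers in the four driver categories: `elevation` (low-pass
#' filtered noise), `slope`/`aspect` (finite-difference gradient magnitude
#' and direction), `precipitation` and `temperature` (directional gradients
#' plus smooth noise, temperature with an elevation lapse), `dist_built` and
#' `dist_road` (Euclidean distance transforms from seeded points/lines), and
#' four piecewise-constant "county" layers (`pop_density`, `gdp`,
#' `agri_output`, `livestock_density`) on a rectangular block partition.
#'
#' @param shape Integer length-2, at least 32x32.
#' @param seed Integer seed; same seed and params give identical stacks.
#' @param params Configuration list as from [scenario_config()].
#' @return Named list of raw (unstandardized) matrices.
#' @export
generate_drivers <- function(shape = c(256L, 256L), seed = 1L,
                             params = scenario_config()) {
  stopifnot(length(shape) == 2L, all(shape >= 32L))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (params$county_block > min(nr, nc))
    stop("county_block larger than grid")
  smooth <- function(m, passes, half) {
    ones <- matrix(1, nrow(m), ncol(m))
    norm <- focal_sum(ones, half)
    for (i in seq_len(passes)) m <- focal_sum(m, half) / norm
    m
  }
  elev_scale <- if (is.null(params$elev_scale)) 1 else params$elev_scale
  elevation <- withr::with_seed(sub_seed(seed, 1L), {
    elev_scale * smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                        params$smooth_passes_elev, params$smooth_half)
  })
  gy <- (shift_mat(elevation, -1, 0, fill = NA) -
         shift_mat(elevation, 1, 0, fill = NA)) / 2
  gx <- (shift_mat(elevation, 0, -1, fill = NA) -
         shift_mat(elevation, 0, 1, fill = NA)) / 2
  gy[is.na(gy)] <- 0; gx[is.na(gx)] <- 0
  slope <- sqrt(gx^2 + gy^2)
  aspect <- atan2(gy, gx)
  rowg <- matrix(seq(0, 1, length.out = nr), nr, nc)        # 0 north, 1 south
  colg <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  precipitation <- withr::with_seed(sub_seed(seed, 2L), {
    0.7 * (rowg + colg) / 2 +
      0.3 * smooth(matrix(stats::rnorm(nr * nc), nr, nc), 3L,
                   params$smooth_half)
  })
  temperature <- withr::with_seed(sub_seed(seed, 3L), {
    0.5 * rowg - 0.2 * colg - 0.4 * elevation +
      0.2 * smooth(matrix(stats::rnorm(nr * nc), nr, nc), 3L,
                   params$smooth_half)
  })
  dist_to_points <- function(pts_r, pts_c) {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d <- matrix(Inf, nr, nc)
    for (i in seq_along(pts_r))
      d <- pmin(d, sqrt((rr - pts_r[i])^2 + (cc - pts_c[i])^2))
    d
  }
  dist_built <- withr::with_seed(sub_seed(seed, 4L), {
    dist_to_points(sample.int(nr, params$n_built_points, replace = TRUE),
                   sample.int(nc, params$n_built_points, replace = TRUE))
  })
  dist_road <- withr::with_seed(sub_seed(seed, 5L), {
    rows <- sample.int(nr, ceiling(params$n_road_lines / 2))
    cols <- sample.int(nc, floor(params$n_road_lines / 2))
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d <- matrix(Inf, nr, nc)
    for (r0 in rows) d <- pmin(d, abs(rr - r0))
    for (c0 in cols) d <- pmin(d, abs(cc - c0))
    d
  })
  br <- ceiling(seq_len(nr) / params$county_block)
  bc <- ceiling(seq_len(nc) / params$county_block)
  county_of <- cbind(rep(br, times = nc), rep(bc, each = nr))
  expand <- function(vals) matrix(vals[county_of], nr, nc)
  # counties are either predominantly agricultural or pastoral, so the two
  # sector-output layers are bimodal and anti-correlated at county level
  ag_county <- withr::with_seed(sub_seed(seed, 6L),
    matrix(stats::rbinom(max(br) * max(bc), 1L, 0.5), max(br), max(bc)))
  county_layer <- function(stream, meanlog, sdlog) {
    withr::with_seed(sub_seed(seed, stream), {
      expand(matrix(stats::rlnorm(max(br) * max(bc), meanlog, sdlog),
                    max(br), max(bc)))
    })
  }
  sector_layer <- function(stream, type_match) {
    withr::with_seed(sub_seed(seed, stream), {
      ml <- 2 + 1.2 * (if (type_match) ag_county else 1L - ag_county)
      expand(matrix(stats::rlnorm(max(br) * max(bc), ml, 0.5),
                    max(br), max(bc)))
    })
  }
  list(elevation = elevation, slope = slope, aspect = aspect,
       precipitation = precipitation, temperature = temperature,
       dist_built = dist_built, dist_road = dist_road,
       pop_density = county_layer(7L, 3, 0.8),
       gdp = county_layer(8L, 5, 1.0),
       agri_output = sector_layer(9L, TRUE),
       livestock_density = sector_layer(10L, FALSE))
}

#' Linear predictors of every class at every cell
#' @noRd
class_linear_predictors <- function(drivers, beta) {
  nms <- colnames(beta)[-1]
  missing <- setdiff(nms, names(drivers$layers))
  if (length(missing))
    stop("missing driver layer(s): ", paste(missing, collapse = ", "))
  n <- length(drivers$layers[[1]])
  X <- cbind(1, vapply(nms, function(nm) as.vector(drivers$layers[[nm]]),
                       numeric(n)))
  X %*% t(beta)    # n_cells x n_classes
}

#' Calibrate intercepts so mean softmax probabilities hit composition targets
#' @noRd
calibrate_intercepts <- function(drivers, beta, targets, iters = 40L) {
  targets <- targets / sum(targets)
  for (it in seq_len(iters)) {
    eta <- class_linear_predictors(drivers, beta)
    eta <- eta - apply(eta, 1, max)
    p <- exp(eta); p <- p / rowSums(p)
    beta[, 1] <- beta[, 1] + log(targets / colMeans(p))
  }
  beta
}

#' Draw the initial land-cover map from known logistic coefficients
#'
#' Samples each cell's class from the softmax of the per-class linear
#' predictors, then applies 3x3 majority smoothing to create contiguous
#' patches. If a configured class is lost by smoothing the draw is retried
#' (bounded) with a perturbed sub-seed.
#'
#' @param drivers A standardized `driver_stack`.
#' @param beta Coefficient matrix as from [scenario_true_beta()] (calibrated).
#' @param seed Integer seed.
#' @param smoothing_passes Number of 3x3 majority passes.
#' @param cell_size Cell size in metres for the returned grid.
#' @param label Epoch label of the returned grid.
#' @return A [lulc_grid] containing every class of `beta`.
#' @export
generate_initial_map <- function(drivers, beta, seed = 1L,
                                 smoothing_passes = 2L, cell_size = 500,
                                 label = "t0") {
  eta <- class_linear_predictors(drivers, beta)
  n <- nrow(eta); k <- ncol(eta)
  dims <- dim(drivers$layers[[1]])
  for (try in 0:4) {
    cls <- withr::with_seed(sub_seed(seed, 10L + try), {
      g <- matrix(-log(-log(stats::runif(n * k))), n, k)  # Gumbel trick
      max.col(eta + g, ties.method = "first")
    })
    m <- matrix(as.integer(cls), dims[1], dims[2])
    before <- unique(as.vector(m))
    for (s in seq_len(smoothing_passes)) m <- majority_smooth(m, k)
    # a class may legitimately be absent from the draw itself (extreme
    # intercepts); only a class erased by smoothing triggers a retry
    if (all(before %in% unique(as.vector(m))))
      return(lulc_grid(m, cell_size = cell_size, label = label))
  }
  stop("a configured class is missing after smoothing; ",
       "coefficients too degenerate")
}

#' One 3x3 majority-filter pass over a class map
#' @noRd
majority_smooth <- function(m, k) {
  counts <- vapply(seq_len(k),
                   function(j) as.vector(focal_sum((m == j) * 1, 1L)),
                   numeric(length(m)))
  matrix(as.integer(max.col(counts, ties.method = "first")),
         nrow(m), ncol(m))
}

#' Advance a land-cover map one step under a known transition matrix
#'
#' Each cell's destination class is drawn independently from its origin
#' class's row of `P`, so realized aggregate transition frequencies converge
#' to `P` as the cell count grows. Within each origin class the drawn
#' destination multiset is then re-matched to cells by suitability: cells
#' with the highest linear predictor for a destination class are the ones
#' that move to it, giving spatially coherent change. Deterministic for a
#' fixed seed; nodata cells are untouched.
#'
#' @param grid A [lulc_grid].
#' @param drivers Standardized `driver_stack`.
#' @param beta Coefficient matrix over the grid's classes.
#' @param P Row-stochastic transition matrix (rows = origin class).
#' @param seed Integer seed.
#' @param label Label for the returned grid.
#' @return A [lulc_grid].
#' @export
evolve_map <- function(grid, drivers, beta, P, seed = 1L, label = "t+1") {
  stopifnot(is_lulc_grid(grid))
  k <- nrow(P)
  if (any(P < 0) || any(P > 1) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("P is not row-stochastic")
  eta <- class_linear_predictors(drivers, beta)
  codes <- grid$codes
  out <- codes
  withr::with_seed(sub_seed(seed, 20L), {
    for (i in seq_len(k)) {
      idx <- which(!is.na(codes) & codes == i)
      if (!length(idx)) next
      dest <- sample.int(k, length(idx), replace = TRUE, prob = P[i, ])
      movers <- idx[dest != i]
      mdest <- dest[dest != i]
      out[idx] <- i
      if (!length(movers)) next
      # re-match drawn destinations to cells by suitability rank
      remaining <- seq_along(movers)
      for (j in order(tabulate(mdest, k), decreasing = TRUE)) {
        mj <- sum(mdest == j)
        if (mj == 0L || j == i) next
        sc <- eta[movers[remaining], j]
        take <- remaining[order(sc, decreasing = TRUE)[seq_len(mj)]]
        out[movers[take]] <- j
        remaining <- setdiff(remaining, take)
      }
    }
  })
  lulc_grid(out, cell_size = grid$cell_size, label = label,
            legend = grid$legend, origin = grid$origin)
}

#' Generate a complete synthetic scenario with ground truth
#'
#' Builds the driver stack, calibrates intercepts to the composition
#' targets, draws the initial map, and advances it twice under the true
#' transition matrix, yielding maps at three dates a decade apart.
#'
#' @param seed Integer seed; same seed + config gives an identical scenario.
#' @param config Configuration list from [scenario_config()].
#' @param true_beta,true_P Ground-truth parameters (defaults:
#'   [scenario_true_beta()], [scenario_true_P()]).
#' @return Object of class `lulc_scenario`: list with `grids` (t0/t1/t2),
#'   `drivers` (standardized stack), `true_beta` (calibrated), `true_P`,
#'   `seed`, `config`.
#' @export
generate_scenario <- function(seed = 1L, config = scenario_config(),
                              true_beta = scenario_true_beta(),
                              true_P = scenario_true_P()) {
  raw <- generate_drivers(config$shape, seed, config)
  ref <- lulc_grid(matrix(1L, config$shape[1], config$shape[2]),
                   cell_size = config$cell_size)
  drivers <- align_and_stack(raw, ref, standardize = TRUE)
  beta <- calibrate_intercepts(drivers, true_beta, config$composition)
  t0 <- generate_initial_map(drivers, beta, seed = seed,
                             smoothing_passes = config$map_smoothing_passes,
                             cell_size = config$cell_size,
                             label = config$labels[1])
  t1 <- evolve_map(t0, drivers, beta, true_P, seed = seed + 1L,
                   label = config$labels[2])
  t2 <- evolve_map(t1, drivers, beta, true_P, seed = seed + 2L,
                   label = config$labels[3])
  structure(list(grids = list(t0 = t0, t1 = t1, t2 = t2),
                 drivers = drivers, true_beta = beta, true_P = true_P,
                 seed = seed, config = config),
            class = "lulc_scenario")
}

#' @export
print.lulc_scenario <- function(x, ...) {
  cat(sprintf("<lulc_scenario seed %d: %s>\n", x$seed,
              paste(vapply(x$grids, function(g) g$label, ""),
                    collapse = " -> ")))
  invisible(x)
}
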