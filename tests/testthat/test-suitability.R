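make_obs <- function(n, beta = NULL, seed = 1) {
  # direct Bernoulli-logistic draws on standardized noise drivers
  withr::with_seed(seed, {
    x1 <- rnorm(n); x2 <- rnorm(n)
    eta <- if (is.null(beta)) rep(0, n) else beta[1] * x1 + beta[2] * x2
    y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
    data.frame(cell = seq_len(n), code = ifelse(y == 1, 1L, 2L),
               x1 = x1, x2 = x2)
  })
}

test_that("stratified sampling is reproducible and reads the lattice", {
  sc <- cached_scenario(seed = 1, small = TRUE)
  g <- sc$grids$t0
  obs <- suppressWarnings(
    sample_observations(g, sc$drivers, n_per_class = 50L, seed = 7))
  obs2 <- suppressWarnings(
    sample_observations(g, sc$drivers, n_per_class = 50L, seed = 7))
  expect_identical(obs, obs2)
  # driver values equal direct lattice lookup at the sampled cells
  expect_equal(obs$elevation, sc$drivers$layers$elevation[obs$cell])
  expect_equal(obs$code, g$codes[obs$cell])
  # a single-class grid yields all-1 responses for it, all-0 for others
  uni <- toy_grid(matrix(1L, 10, 10))
  duni <- align_and_stack(list(z = matrix(rnorm(100), 10, 10)), uni)
  obs_u <- suppressWarnings(sample_observations(uni, duni, 30L, seed = 1))
  expect_true(all(obs_u$code == 1L))
  expect_error(fit_class_logistic(obs_u, 1), "degenerate response")
})

test_that("null drivers give near-zero coefficients and chance-level ROC", {
  obs <- make_obs(1e4, beta = NULL, seed = 2)
  m <- fit_class_logistic(obs, 1L, seed = 2)
  expect_true(all(abs(m$coefficients) < 0.1))
  expect_gte(m$roc, 0.45)
  expect_lte(m$roc, 0.60)
})

test_that("known coefficients are recovered within 0.2 at n = 1e4", {
  obs <- make_obs(1e4, beta = c(2, -1), seed = 3)
  m <- fit_class_logistic(obs, 1L, balance = FALSE, seed = 3)
  expect_lt(abs(m$coefficients[["x1"]] - 2), 0.2)
  expect_lt(abs(m$coefficients[["x2"]] - (-1)), 0.2)
  expect_true(m$converged)
})

test_that("an exact duplicate driver leaves predictions unchanged", {
  obs <- make_obs(2000, beta = c(1.5, -0.5), seed = 4)
  m1 <- fit_class_logistic(obs, 1L, seed = 4)
  obs$x3 <- obs$x1                       # exact copy
  m2 <- fit_class_logistic(obs, 1L, seed = 4)
  expect_true(all(is.finite(unlist(m2$coefficients))))
  p1 <- m1$intercept + as.matrix(obs[, c("x1", "x2")]) %*%
    unlist(m1$coefficients[c("x1", "x2")])
  p2 <- m2$intercept + as.matrix(obs[, c("x1", "x2", "x3")]) %*%
    unlist(m2$coefficients[c("x1", "x2", "x3")])
  expect_equal(as.vector(p1), as.vector(p2), tolerance = 1e-8)
})

test_that("suitability prediction evaluates the logistic exactly", {
  drv <- structure(list(layers = list(x1 = matrix(2, 2, 2)),
                        standardized = TRUE, cell_size = 500),
                   class = "driver_stack")
  mod <- structure(list(`1` = list(class = 1L, intercept = 0.5,
                                   coefficients = c(x1 = -1),
                                   roc = NA, subset = "x1")),
                   class = "logistic_model_set")
  atlas <- predict_suitability(mod, drv)
  expect_equal(atlas[["1"]][1, 1], 1 / (1 + exp(1.5)), tolerance = 1e-12)

  mod[["1"]]$intercept <- 0; mod[["1"]]$coefficients <- c(x1 = 0)
  expect_equal(predict_suitability(mod, drv)[["1"]][1, 1], 0.5)

  mod[["1"]]$intercept <- 20
  expect_gt(predict_suitability(mod, drv)[["1"]][1, 1], 0.999999)

  mod[["1"]]$coefficients <- c(missing_layer = 1)
  expect_error(predict_suitability(mod, drv), "missing_layer")
})

test_that("suitability is monotone in each driver with the coefficient sign", {
  mod <- structure(list(`1` = list(class = 1L, intercept = 0.2,
                                   coefficients = c(a = 1.3, b = -0.7),
                                   roc = NA, subset = c("a", "b"))),
                   class = "logistic_model_set")
  probe <- seq(-2, 2, length.out = 9)
  for (bval in c(-1, 0, 1)) {
    drv <- structure(list(layers = list(
      a = matrix(probe, 9, 1), b = matrix(bval, 9, 1)),
      standardized = TRUE), class = "driver_stack")
    p <- predict_suitability(mod, drv)[["1"]]
    expect_true(all(diff(p[, 1]) > 0))   # +1.3 coefficient: increasing
  }
  drv <- structure(list(layers = list(a = matrix(0, 9, 1),
                                      b = matrix(probe, 9, 1)),
                        standardized = TRUE), class = "driver_stack")
  expect_true(all(diff(predict_suitability(mod, drv)[["1"]][, 1]) < 0))
})

test_that("ROC area: closed cases, hand example, complement identity", {
  expect_equal(roc_area(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_area(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0.0)
  # 3 concordant of 4 pos-neg pairs
  expect_equal(roc_area(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_area(1:3, c(1, 1, 1)), "both label values")
  withr::with_seed(5, {
    s <- rnorm(50); y <- rbinom(50, 1, 0.4)
    expect_equal(roc_area(s, y) + roc_area(-s, y), 1)
    # independent cross-check against the reference AUC implementation
    expect_equal(roc_area(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  })
})

test_that("driver-subset comparison mirrors the with/without design", {
  sc <- cached_scenario(seed = 1, small = TRUE)
  g <- sc$grids$t1
  full <- scenario_driver_names()
  reduced <- setdiff(full, c("agri_output", "livestock_density"))
  tab <- suppressWarnings(compare_driver_subsets(
    g, sc$drivers, list(full = full, reduced = reduced),
    n_per_class = 300L, seed = 2))
  expect_identical(tab$class, sort(unique(as.vector(g$codes))))
  # cultivated and grassland load on the sector-output layers by construction
  expect_gt(tab$difference[tab$class == 1], 0)
  expect_gt(tab$difference[tab$class == 3], 0)
  # a subset compared with itself gives identical ROC rows
  tab2 <- suppressWarnings(compare_driver_subsets(
    g, sc$drivers, list(a = full, b = full), n_per_class = 200L, seed = 2))
  expect_equal(tab2$a, tab2$b)
  expect_error(
    suppressWarnings(compare_driver_subsets(g, sc$drivers,
                                            list(x = "nope"))), "nope")
  expect_error(compare_driver_subsets(g, sc$drivers, list(character(0))),
               "empty")
})
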