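test_that("driver generator: flat terrain, distance transform, determinism", {
  cfg <- small_scenario_config()
  cfg$elev_scale <- 0
  d <- generate_drivers(c(32L, 32L), seed = 5, params = cfg)
  expect_true(all(d$slope == 0))     # gradient of a constant field

  cfg2 <- small_scenario_config()
  cfg2$n_built_points <- 1L
  d2 <- generate_drivers(c(48L, 48L), seed = 2, params = cfg2)
  db <- d2$dist_built
  at <- which(db == 0, arr.ind = TRUE)
  expect_equal(nrow(at), 1L)         # exactly one seeded built-up point
  rr <- matrix(seq_len(48), 48, 48)
  cc <- matrix(seq_len(48), 48, 48, byrow = TRUE)
  expect_equal(db, sqrt((rr - at[1, 1])^2 + (cc - at[1, 2])^2))

  d3a <- generate_drivers(c(32L, 32L), seed = 9, params = cfg)
  d3b <- generate_drivers(c(32L, 32L), seed = 9, params = cfg)
  expect_identical(d3a, d3b)
  # county blocks: socio-economic layers piecewise constant per block
  blk <- d$pop_density[1:cfg$county_block, 1:cfg$county_block]
  expect_equal(length(unique(as.vector(blk))), 1L)
  expect_error(generate_drivers(c(32L, 32L), 1,
                                within(cfg, county_block <- 64L)), "county")
})

test_that("initial map sampling: uniform null, dominant intercept, seed", {
  ref <- lulc_grid(matrix(1L, 100, 100))
  drv <- align_and_stack(generate_drivers(c(100L, 100L), seed = 3,
                                          params = scenario_config()),
                         ref, standardize = TRUE)
  b0 <- matrix(0, 6, 12,
               dimnames = list(as.character(1:6),
                               c("(Intercept)", scenario_driver_names())))
  m <- generate_initial_map(drv, b0, seed = 4, smoothing_passes = 0L)
  freq <- as.vector(table(m$codes)) / 1e4
  se <- sqrt((1 / 6) * (5 / 6) / 1e4)
  expect_true(all(abs(freq - 1 / 6) < 3 * se))

  bdom <- b0; bdom["2", "(Intercept)"] <- 10
  mdom <- generate_initial_map(drv, bdom, seed = 4, smoothing_passes = 0L)
  expect_gt(mean(mdom$codes == 2L), 0.99)

  m2 <- generate_initial_map(drv, b0, seed = 4, smoothing_passes = 0L)
  expect_identical(m$codes, m2$codes)
})

test_that("evolve_map: identity chain, binomial transition fraction, seed", {
  sc <- cached_scenario(seed = 1, small = TRUE)
  g <- sc$grids$t0
  P_id <- diag(6); dimnames(P_id) <- list(1:6, 1:6)
  out <- evolve_map(g, sc$drivers, sc$true_beta, P_id, seed = 3)
  expect_identical(out$codes, g$codes)

  # all-class-1 map under p(1 -> 3) = 0.2
  shape <- c(200L, 200L)
  drv <- align_and_stack(generate_drivers(shape, seed = 6,
                                          params = scenario_config()),
                         lulc_grid(matrix(1L, shape[1], shape[2])),
                         standardize = TRUE)
  ones <- lulc_grid(matrix(1L, shape[1], shape[2]))
  P <- diag(6); P[1, 1] <- 0.8; P[1, 3] <- 0.2
  dimnames(P) <- list(1:6, 1:6)
  ev <- evolve_map(ones, drv, sc$true_beta, P, seed = 11)
  frac <- mean(ev$codes == 3L)
  n <- prod(shape)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))

  ev2 <- evolve_map(ones, drv, sc$true_beta, P, seed = 11)
  expect_identical(ev$codes, ev2$codes)
  bad <- P; bad[1, 1] <- 0.5
  expect_error(evolve_map(ones, drv, sc$true_beta, bad, seed = 1),
               "row-stochastic")
})

test_that("scenario is reproducible and spatially autocorrelated", {
  a <- cached_scenario(seed = 1, small = TRUE)
  b <- generate_scenario(seed = 1, config = small_scenario_config())
  expect_identical(a$grids$t0$codes, b$grids$t0$codes)
  expect_identical(a$grids$t2$codes, b$grids$t2$codes)
  expect_identical(a$drivers$layers, b$drivers$layers)
  expect_true(all(abs(rowSums(a$true_P) - 1) < 1e-12))
  # every configured class occurs at t0
  expect_setequal(unique(as.vector(a$grids$t0$codes)), 1:6)

  # join counts exceed those of an i.i.d. shuffle of the same composition
  for (s in 1:3) {
    sc <- cached_scenario(seed = s, small = TRUE)
    codes <- sc$grids$t0$codes
    shuf <- withr::with_seed(s, matrix(sample(as.vector(codes)),
                                       nrow(codes), ncol(codes)))
    expect_gt(join_count(codes), join_count(shuf))
  }
})
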