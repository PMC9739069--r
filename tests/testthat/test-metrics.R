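test_that("patch labelling: uniform grid, checkerboard, diagonal pair", {
  uni <- toy_grid(matrix(3L, 6, 6))
  expect_equal(nrow(label_patches(uni, 8L)$patches), 1L)

  chk <- toy_grid(outer(1:6, 1:6, function(r, c) (r + c) %% 2L + 1L))
  expect_equal(nrow(label_patches(chk, 4L)$patches), 36L)

  m <- matrix(1L, 6, 6)
  m[2, 2] <- 2L; m[3, 3] <- 2L       # diagonal pair of class 2
  g <- toy_grid(m)
  p4 <- label_patches(g, 4L)$patches
  p8 <- label_patches(g, 8L)$patches
  expect_equal(sum(p4$class == 2), 2L)
  expect_equal(sum(p8$class == 2), 1L)
  expect_error(label_patches(g, 6L), "connectivity")
})

test_that("labels are deterministic, row-major, and partition valid cells", {
  g <- random_grid(15, 15, k = 4, seed = 21)
  g$codes[c(3, 50)] <- NA_integer_
  lab <- label_patches(g, 8L)
  expect_equal(lab$labels[is.na(g$codes)], c(0L, 0L))
  expect_equal(sort(unique(lab$labels[lab$labels > 0])),
               seq_len(nrow(lab$patches)))
  expect_equal(sum(lab$patches$cells), sum(!is.na(g$codes)))
  # first patch is the one containing the row-major first valid cell
  first_cell <- which(t(!is.na(g$codes)))[1]
  rc <- c((first_cell - 1) %/% 15 + 1, (first_cell - 1) %% 15 + 1)
  expect_equal(lab$labels[rc[1], rc[2]], 1L)
})

test_that("single compact square patch: NP, MPS, LPI, PSCV, AI", {
  m <- matrix(2L, 10, 10)
  m[3:6, 4:7] <- 1L                   # one 4x4 patch of class 1
  g <- toy_grid(m, cell_size = 500)   # 25 ha per cell, A = 2500 ha
  cm <- class_metrics(g)
  r <- cm[cm$class == 1, ]
  expect_equal(r$NP, 1)
  expect_equal(r$MPS_ha, 16 * 25)
  expect_equal(r$LPI_pct, 16)
  expect_equal(r$PSCV, 0)
  expect_equal(r$AI_pct, 100)         # saturates the largest-square bound
})

test_that("two equal quarter-landscape patches give DIVISION 0.875", {
  m <- matrix(2L, 20, 20)
  m[1:10, 1:10] <- 1L
  m[11:20, 11:20] <- 1L               # two 100-cell patches, A = 400
  cm <- class_metrics(toy_grid(m), connectivity = 4L)
  expect_equal(cm$DIVISION[cm$class == 1], 1 - 2 * (1 / 4)^2,
               tolerance = 1e-12)
})

test_that("Shannon diversity: closed-form compositions", {
  expect_equal(landscape_metrics(toy_grid(matrix(1L, 8, 8)))$SHDI, 0)
  half <- toy_grid(matrix(rep(c(1L, 3L), each = 32), 8, 8))
  expect_equal(landscape_metrics(half)$SHDI, log(2), tolerance = 1e-12)
  quarters <- toy_grid(matrix(rep(1:4, each = 16), 8, 8))
  expect_equal(landscape_metrics(quarters)$SHDI, log(4), tolerance = 1e-12)
})

test_that("indices are invariant under translation and 90-degree rotation", {
  m <- random_grid(12, 12, k = 4, seed = 31)$codes
  g <- toy_grid(m)
  rot <- toy_grid(t(m[nrow(m):1, ]))               # 90-degree rotation
  pad <- function(dr, dc) {                         # translation on a canvas
    cv <- matrix(NA_integer_, 16, 16)
    cv[dr + 1:12, dc + 1:12] <- m
    toy_grid(cv)
  }
  for (other in list(rot, pad(0, 0), pad(3, 2))) {
    expect_equal(class_metrics(g), class_metrics(other), tolerance = 1e-12)
    expect_equal(landscape_metrics(g), landscape_metrics(other),
                 tolerance = 1e-12)
  }
})

test_that("splitting a patch raises NP and DIVISION, lowers AI", {
  m <- matrix(2L, 9, 9)
  m[4:6, 1:9] <- 1L                  # one horizontal band of class 1
  g <- toy_grid(m)
  m2 <- m
  m2[4:6, 5] <- 2L                   # one-cell corridor cuts the band
  g2 <- toy_grid(m2)
  a <- class_metrics(g); b <- class_metrics(g2)
  expect_gt(b$NP[b$class == 1], a$NP[a$class == 1])
  expect_gt(b$DIVISION[b$class == 1], a$DIVISION[a$class == 1])
  expect_lte(b$AI_pct[b$class == 1], a$AI_pct[a$class == 1])
})

test_that("every index matches the brute-force oracle on random grids", {
  # 40 grids here; the full 200-grid sweep runs in the acceptance suite
  for (i in 1:40) {
    k <- 3 + (i %% 4)
    g <- random_grid(15, 15, k = k, seed = 100 + i)
    conn <- if (i %% 2 == 0) 4L else 8L
    cm <- class_metrics(g, connectivity = conn)
    om <- oracle_class_metrics(g$codes, 500, conn)
    expect_equal(cm$NP, om$NP)
    expect_equal(cm$MPS_ha, om$MPS_ha, tolerance = 1e-9)
    expect_equal(cm$LPI_pct, om$LPI_pct, tolerance = 1e-9)
    expect_equal(cm$PSCV, om$PSCV, tolerance = 1e-9)
    expect_equal(cm$DIVISION, om$DIVISION, tolerance = 1e-9)
    expect_equal(cm$AI_pct, om$AI_pct, tolerance = 1e-9)
    lm_ <- landscape_metrics(g, connectivity = conn)
    ol <- oracle_landscape_metrics(g$codes, 500, conn)
    expect_equal(lm_$NP, ol$NP)
    expect_equal(unlist(lm_[-1]), unlist(ol[-1]), tolerance = 1e-9)
  }
})

test_that("metrics change table reports absolute and percent change", {
  g1 <- random_grid(10, 10, k = 3, seed = 41)
  g1$label <- "2000"
  g2 <- random_grid(10, 10, k = 3, seed = 42)
  g2$label <- "2030"
  ch <- metrics_change(metrics_report(g1), metrics_report(g2))
  np <- ch[ch$index == "NP", ]
  expect_equal(np$change, np$last - np$first)
  expect_equal(np$change_pct, 100 * (np$last - np$first) / np$first)
})
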