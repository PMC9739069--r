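# Shared fixtures: toy grids, a cached default scenario, and independent
# brute-force oracles (flood-fill patch enumeration, explicit adjacency
# counting) for the landscape metrics.

toy_grid <- function(m, cell_size = 500, label = "", legend = NULL) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  if (is.null(legend)) legend <- lulc_legend()
  lulc_grid(m, cell_size = cell_size, label = label, legend = legend)
}

random_grid <- function(nr, nc, k = 6, seed = 1, cell_size = 500) {
  withr::with_seed(seed, {
    toy_grid(matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc),
             cell_size = cell_size)
  })
}

# small scenario for fast unit tests (full 256x256 used where the spec asks)
small_scenario_config <- function() {
  cfg <- scenario_config()
  cfg$shape <- c(64L, 64L)
  cfg$county_block <- 16L
  cfg
}

.fixtures <- new.env(parent = emptyenv())

cached_scenario <- function(seed = 1L, small = FALSE) {
  key <- paste0("sc_", seed, "_", small)
  if (is.null(.fixtures[[key]])) {
    cfg <- if (small) small_scenario_config() else scenario_config()
    .fixtures[[key]] <- generate_scenario(seed = seed, config = cfg)
  }
  .fixtures[[key]]
}

# ---- brute-force landscape-metric oracle -----------------------------------

oracle_patches <- function(codes, connectivity = 8L) {
  nr <- nrow(codes); nc <- ncol(codes)
  nbrs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    nbrs <- c(nbrs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  seen <- matrix(FALSE, nr, nc)
  patches <- list()
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    if (is.na(codes[r, cl]) || seen[r, cl]) next
    k <- codes[r, cl]
    stack <- list(c(r, cl)); seen[r, cl] <- TRUE; count <- 0L
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      count <- count + 1L
      for (d in nbrs) {
        rr <- cur[1] + d[1]; cc <- cur[2] + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !seen[rr, cc] && !is.na(codes[rr, cc]) && codes[rr, cc] == k) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    patches[[length(patches) + 1L]] <- list(class = k, cells = count)
  }
  patches
}

# explicit pairwise rook adjacency count of like-coded cells of class k
oracle_like_adj <- function(codes, k) {
  nr <- nrow(codes); nc <- ncol(codes)
  g <- 0L
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    if (is.na(codes[r, cl]) || codes[r, cl] != k) next
    if (r < nr && !is.na(codes[r + 1, cl]) && codes[r + 1, cl] == k)
      g <- g + 1L
    if (cl < nc && !is.na(codes[r, cl + 1]) && codes[r, cl + 1] == k)
      g <- g + 1L
  }
  g
}

oracle_max_adj <- function(A) {
  n <- floor(sqrt(A)); m <- A - n^2
  if (m == 0) 2 * n * (n - 1)
  else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
  else 2 * n * (n - 1) + 2 * m - 2
}

oracle_class_metrics <- function(codes, cell_size = 500, connectivity = 8L) {
  pats <- oracle_patches(codes, connectivity)
  cell_ha <- cell_size^2 / 1e4
  areas <- vapply(pats, function(p) p$cells * cell_ha, numeric(1))
  cls <- vapply(pats, function(p) p$class, numeric(1))
  A <- sum(areas)
  classes <- sort(unique(cls))
  do.call(rbind, lapply(classes, function(k) {
    a <- areas[cls == k]
    mps <- mean(a)
    cells_k <- sum(a) / cell_ha
    g <- oracle_like_adj(codes, k)
    gmax <- oracle_max_adj(cells_k)
    data.frame(class = k, NP = length(a), MPS_ha = mps,
               LPI_pct = 100 * max(a) / A,
               PSCV = if (mps > 0) 100 * sqrt(mean((a - mps)^2)) / mps else 0,
               DIVISION = 1 - sum((a / A)^2),
               AI_pct = if (gmax > 0) 100 * g / gmax else 0)
  }))
}

oracle_landscape_metrics <- function(codes, cell_size = 500,
                                     connectivity = 8L) {
  pats <- oracle_patches(codes, connectivity)
  cell_ha <- cell_size^2 / 1e4
  areas <- vapply(pats, function(p) p$cells * cell_ha, numeric(1))
  cls <- vapply(pats, function(p) p$class, numeric(1))
  A <- sum(areas)
  cm <- oracle_class_metrics(codes, cell_size, connectivity)
  p_i <- vapply(cm$class, function(k) sum(areas[cls == k]) / A, numeric(1))
  mps <- mean(areas)
  data.frame(NP = length(areas), MPS_ha = mps,
             LPI_pct = 100 * max(areas) / A,
             PSCV = if (mps > 0) 100 * sqrt(mean((areas - mps)^2)) / mps
                    else 0,
             AI_pct = sum(p_i * cm$AI_pct),
             SHDI = -sum(p_i * log(p_i)))
}

# like-coded rook join count of a whole map (spatial autocorrelation probe)
join_count <- function(codes) {
  sum(vapply(sort(unique(codes[!is.na(codes)])),
             function(k) oracle_like_adj(codes, k), integer(1)))
}
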