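# CA spatial allocation: Markov targets fix *how much* of each class the
# next map contains; suitability x neighbourhood ranking decides *where*.
# Each cycle interpolates the quota toward the final targets, recomputes
# neighbourhood weights on the current map, and lets deficit classes claim
# the best-ranked cells of surplus classes.

#' CA configuration
#'
#' @param filter_size Odd window width of the contiguity filter (default 5).
#' @param cycles Number of allocation cycles (default 10).
#' @param seed Integer seed (used when `tiebreak = "random"`).
#' @param neighbor_floor Floor added to the neighbourhood weight so isolated
#'   growth is possible (default 0.01).
#' @param tiebreak `"deterministic"` (higher transition potential, then
#'   row-major cell index) or `"random"` (seeded jitter of tied potentials).
#' @return Object of class `ca_config`.
#' @export
ca_config <- function(filter_size = 5L, cycles = 10L, seed = 1L,
                      neighbor_floor = 0.01, tiebreak = "deterministic") {
  stopifnot(filter_size %% 2L == 1L, filter_size >= 3L, cycles >= 1L,
            neighbor_floor > 0, neighbor_floor < 1,
            tiebreak %in% c("deterministic", "random"))
  structure(list(filter_size = as.integer(filter_size),
                 cycles = as.integer(cycles), seed = as.integer(seed),
                 neighbor_floor = neighbor_floor, tiebreak = tiebreak),
            class = "ca_config")
}

#' Neighbourhood weight of a class
#'
#' Fraction of valid cells within the `filter_size` x `filter_size` window
#' centred at each cell that carry code `class`, floored at `floor_eps`.
#' Windows are truncated at the lattice edge (no wraparound).
#'
#' @param grid A [lulc_grid].
#' @param class Class code.
#' @param filter_size Odd window width.
#' @param floor_eps Lower bound of the weight.
#' @return Matrix in `[floor_eps, 1]`.
#' @export
neighborhood_weight <- function(grid, class, filter_size = 5L,
                                floor_eps = 0.01) {
  stopifnot(is_lulc_grid(grid), filter_size %% 2L == 1L)
  half <- (filter_size - 1L) %/% 2L
  valid <- !is.na(grid$codes)
  hits <- focal_sum((valid & grid$codes == class) * 1, half)
  tot <- focal_sum(valid * 1, half)
  w <- hits / pmax(tot, 1)
  w[w < floor_eps] <- floor_eps
  w
}

#' Allocate Markov quantities on the lattice
#'
#' Targets are the largest-remainder-rounded one-step Markov projection of
#' the input composition, so they are exactly feasible. Per cycle, the
#' interim quota moves linearly from the input counts to the targets; the
#' transition potential of class k at cell x is `atlas[[k]](x) *
#' neighborhood_weight(k)(x)`; deficit classes (quota above count),
#' processed in descending-deficit order, claim cells currently held by
#' surplus classes in descending-potential order. A cell is reassigned at
#' most once per cycle and never to a class whose suitability there is zero.
#' Final per-class counts equal the targets exactly; nodata is untouched.
#'
#' @param grid_t A [lulc_grid] at the start date.
#' @param atlas `suitability_atlas` congruent with the grid.
#' @param model `transition_model` over the grid's classes.
#' @param cfg A [ca_config()].
#' @param label Label for the output grid.
#' @return A [lulc_grid] with attribute `"ca_log"` (per-cycle quota and
#'   reassignment counts).
#' @export
simulate_ca <- function(grid_t, atlas, model, cfg = ca_config(),
                        label = "simulated") {
  stopifnot(is_lulc_grid(grid_t), inherits(atlas, "suitability_atlas"),
            inherits(model, "transition_model"), inherits(cfg, "ca_config"))
  classes <- model$classes
  if (!setequal(as.character(classes), names(atlas)))
    stop("atlas classes do not match transition model classes")
  codes <- grid_t$codes
  valid <- which(!is.na(codes))
  n0 <- class_counts(grid_t)
  targets <- markov_targets(model, grid_t)
  m <- codes
  log_rows <- list()
  jitter <- NULL
  if (cfg$tiebreak == "random")
    jitter <- withr::with_seed(cfg$seed,
                               stats::runif(length(codes), 0, 1e-9))
  for (cyc in seq_len(cfg$cycles)) {
    frac <- cyc / cfg$cycles
    quota <- largest_remainder(n0 + frac * (targets - n0),
                               total = length(valid))
    cur <- as.integer(table(factor(m[valid], levels = classes)))
    deficit <- quota - cur
    if (all(deficit == 0L)) {
      log_rows[[cyc]] <- data.frame(cycle = cyc, reassigned = 0L)
      next
    }
    # per-class transition potential on the current map
    tp <- lapply(seq_along(classes), function(ki) {
      gcur <- lulc_grid(m, cell_size = grid_t$cell_size,
                        legend = grid_t$legend)
      w <- neighborhood_weight(gcur, classes[ki], cfg$filter_size,
                               cfg$neighbor_floor)
      p <- atlas[[as.character(classes[ki])]] * w
      if (!is.null(jitter)) p <- p + jitter
      p
    })
    donor_room <- pmax(cur - quota, 0L)      # cells each surplus class may lose
    taken <- rep(FALSE, length(codes))       # reassigned this cycle
    moved <- 0L
    for (ki in order(deficit, decreasing = TRUE)) {
      need <- deficit[ki]
      if (need <= 0L) break
      k <- classes[ki]
      # candidate cells: held by a class that can still donate, untouched
      cand <- valid[donor_room[match(m[valid], classes)] > 0L &
                      !taken[valid] & m[valid] != k]
      if (!length(cand)) next
      pk <- tp[[ki]][cand]
      cand <- cand[pk > 0]
      pk <- pk[pk > 0]
      # row-major index breaks exact-potential ties deterministically
      nr <- nrow(m)
      rowmaj <- ((cand - 1L) %% nr) * ncol(m) + ((cand - 1L) %/% nr)
      ord <- order(-pk, rowmaj)
      for (ci in ord) {
        if (need == 0L) break
        cell <- cand[ci]
        di <- match(m[cell], classes)
        if (donor_room[di] > 0L) {
          donor_room[di] <- donor_room[di] - 1L
          m[cell] <- k
          taken[cell] <- TRUE
          need <- need - 1L
          moved <- moved + 1L
        }
      }
      deficit[ki] <- need
    }
    log_rows[[cyc]] <- data.frame(cycle = cyc, reassigned = moved)
  }
  final <- as.integer(table(factor(m[valid], levels = classes)))
  if (!all(final == targets))
    stop("internal error: allocated counts do not meet Markov targets")
  out <- lulc_grid(m, cell_size = grid_t$cell_size, label = label,
                   legend = grid_t$legend, origin = grid_t$origin)
  attr(out, "ca_log") <- do.call(rbind, log_rows)
  attr(out, "targets") <- targets
  out
}
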