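# Internal lattice helpers shared by the generator, the CA and the metrics.

#' Shift a matrix by (dr, dc), padding with `fill`
#'
#' Cells shifted in from outside the lattice take `fill`. Used for
#' neighbourhood sums and adjacency counting; no wraparound.
#' @noRd
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)   # destination rows
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Sum over a (2*half+1)^2 moving window, truncated at edges
#' @noRd
focal_sum <- function(m, half) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -half:half)
    for (dc in -half:half)
      acc <- acc + shift_mat(m, dr, dc, fill = 0)
  acc
}

#' Largest-remainder rounding of non-negative reals to integers with fixed sum
#'
#' Returns integers summing exactly to `total` (default: round(sum(x))).
#' Fractional-part ties broken by position order.
#' @noRd
largest_remainder <- function(x, total = NULL) {
  stopifnot(all(x >= 0))
  if (is.null(total)) total <- round(sum(x))
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(x - f, decreasing = TRUE)  # stable: ties by position
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(x - f, decreasing = FALSE)
    k <- 0; i <- 1
    while (k < -rem) {            # only take from strictly positive entries
      j <- ord[i]
      if (f[j] > 0) { f[j] <- f[j] - 1; k <- k + 1 }
      i <- i + 1
    }
  }
  as.integer(f)
}

#' Derive a bounded sub-seed from a base seed and a stream index
#' @noRd
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 97L + as.integer(stream) * 1009L
}
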