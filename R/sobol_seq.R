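# Sobol low-discrepancy sequences (Gray-code construction, direction numbers
# from the Joe-Kuo tables, first 21 dimensions).

# degree s, polynomial coefficient a, initial direction integers m
.SOBOL_TABLE <- list(
  list(s = 1L, a = 0L, m = 1L),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L)),
  list(s = 5L, a = 11L, m = c(1L, 1L, 5L, 1L, 1L)),
  list(s = 5L, a = 13L, m = c(1L, 1L, 1L, 3L, 11L)),
  list(s = 5L, a = 14L, m = c(1L, 3L, 5L, 5L, 31L)),
  list(s = 6L, a = 1L, m = c(1L, 3L, 3L, 9L, 7L, 49L)),
  list(s = 6L, a = 13L, m = c(1L, 1L, 1L, 15L, 21L, 21L)),
  list(s = 6L, a = 16L, m = c(1L, 3L, 1L, 13L, 27L, 49L)),
  list(s = 6L, a = 19L, m = c(1L, 1L, 1L, 15L, 7L, 5L)),
  list(s = 6L, a = 22L, m = c(1L, 3L, 1L, 15L, 13L, 25L)),
  list(s = 6L, a = 25L, m = c(1L, 1L, 5L, 5L, 19L, 61L)),
  list(s = 7L, a = 1L, m = c(1L, 3L, 7L, 11L, 23L, 15L, 103L)),
  list(s = 7L, a = 4L, m = c(1L, 3L, 7L, 13L, 13L, 15L, 69L)))

.SOBOL_BITS <- 31L

# Direction integers v_k = m_k * 2^(BITS - k) for one dimension (31 bits).
.sobol_directions <- function(dim_entry, n_bits = .SOBOL_BITS) {
  if (is.null(dim_entry)) {        # first dimension: van der Corput base 2
    m <- rep(1L, n_bits)
  } else {
    s <- dim_entry$s
    m <- integer(n_bits)
    m[seq_len(s)] <- dim_entry$m
    a_bits <- as.integer(intToBits(dim_entry$a))[seq_len(max(s - 1L, 1L))]
    for (k in (s + 1L):n_bits) {
      v <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
      if (s > 1L) {
        for (i in seq_len(s - 1L)) {
          if (a_bits[s - i] == 1L) v <- bitwXor(v, bitwShiftL(m[k - i], i))
        }
      }
      m[k] <- v
    }
  }
  vapply(seq_len(n_bits), function(k) bitwShiftL(m[k], n_bits - k), integer(1))
}

#' Sobol quasi-random points
#'
#' Gray-code Sobol sequence in up to 21 dimensions, optionally digitally
#' shifted (a seeded XOR with a random 31-bit integer per dimension) so that
#' independent replicates can be drawn. The unshifted sequence starts at the
#' second point (the all-zero first point is skipped).
#'
#' @param n Number of points.
#' @param d Dimension (<= 21).
#' @param seed Optional integer; if given, applies a seeded digital shift.
#' @param skip Number of initial points to skip (default 1).
#' @return An `n x d` matrix with entries in `[0, 1)`.
#' @export
sobol_points <- function(n, d, seed = NULL, skip = 1L) {
  if (d > length(.SOBOL_TABLE) + 1L) {
    stop("Sobol direction numbers available for at most ",
         length(.SOBOL_TABLE) + 1L, " dimensions; got d = ", d)
  }
  V <- vapply(seq_len(d), function(j) {
    .sobol_directions(if (j == 1L) NULL else .SOBOL_TABLE[[j - 1L]])
  }, integer(.SOBOL_BITS))                       # BITS x d
  total <- n + skip
  X <- matrix(0L, total, d)
  state <- integer(d)
  for (i in seq_len(total - 1L)) {
    c_bit <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c_bit <- c_bit + 1L }
    state <- bitwXor(state, V[c_bit, ])
    X[i + 1L, ] <- state
  }
  X <- X[(skip + 1L):total, , drop = FALSE]
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
    shift <- vapply(seq_len(d), function(j) {
      as.integer(sum(bitwShiftL(1L, which(stats::runif(.SOBOL_BITS) < 0.5) - 1L)))
    }, integer(1))
    X <- t(apply(X, 1L, function(row) bitwXor(row, shift)))
    if (d == 1L) X <- matrix(X, ncol = 1L)
  }
  X / 2^.SOBOL_BITS
}
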