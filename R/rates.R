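# Deterministic vector field and stochastic propensities, both derived from
# the same mass-action network.

#' Volume-free (intensive) mass-action rates
#'
#' The scaled propensity of each reaction at concentration `x` (nM):
#' `k` (zeroth order), `k*x_i` (first, times the modifier level if present),
#' `k*x_i*x_j`, `k*x_i^2`, `k*x_i^3`. These are the rates whose
#' stoichiometry-weighted sum is the deterministic vector field, and the
#' `omega -> Inf` limit of `propensities(X)/omega` at `X = omega*x`.
#'
#' @param net A [reaction_network()].
#' @param x Non-negative concentration vector (nM), in species order.
#' @return Numeric vector, one intensive rate per reaction.
#' @export
scaled_propensities <- function(net, x) {
  .check_state(net, x)
  .scaled_prop_fast(net$tables, .rates(net), x)
}

# hot path: no validation, precomputed tables and effective rates
.scaled_prop_fast <- function(tb, k, x) {
  x1 <- x[tb$idx1s]
  out <- k
  kd <- tb$kind
  f <- kd == 2L; if (any(f)) out[f] <- k[f] * x1[f]
  f <- kd == 3L; if (any(f)) out[f] <- k[f] * x1[f] * x[tb$idx2s][f]
  f <- kd == 4L; if (any(f)) out[f] <- k[f] * x1[f] * x1[f]
  f <- kd == 5L; if (any(f)) out[f] <- k[f] * x1[f]^3
  out
}

.rhs_fast <- function(tb, k, x) {
  drop(tb$stoich %*% .scaled_prop_fast(tb, k, x))
}

#' Deterministic mass-action vector field
#'
#' Right-hand side of `dx/dt = b(x)`: the stoichiometry matrix applied to the
#' intensive rates, `b(x) = sum_j nu_j * a~_j(x)`.
#'
#' @inheritParams scaled_propensities
#' @return Named concentration-rate vector (nM per model time unit).
#' @export
ode_rhs <- function(net, x) {
  a <- scaled_propensities(net, x)
  drop(net$tables$stoich %*% a)
}

#' Stochastic propensity functions
#'
#' Firing rates of the Markov jump process at molecule counts `X`, following
#' the volume-scaled mass-action convention: `omega*k` (zeroth),
#' `k*X_i` (first, times modifier), `k/omega * X_i*X_j` (hetero),
#' `k/omega * X_i*(X_i-1)` (homodimerisation, no 1/2 symmetry factor),
#' `k/omega^2 * X_i*(X_i-1)*(X_i-2)` (trimolecular extension).
#'
#' @param net A [reaction_network()].
#' @param X Non-negative integer count vector, in species order.
#' @param size A [system_size()].
#' @return Numeric vector of non-negative rates, one per reaction.
#' @export
propensities <- function(net, X, size) {
  .check_state(net, X)
  stopifnot(inherits(size, "system_size"))
  om <- size$omega
  tb <- net$tables
  k <- .rates(net)
  X1 <- ifelse(tb$idx1 > 0L, X[pmax(tb$idx1, 1L)], 1)
  out <- numeric(length(k))
  kd <- tb$kind
  out[kd == 1L] <- om * k[kd == 1L]
  out[kd == 2L] <- k[kd == 2L] * X1[kd == 2L]
  sh <- kd == 3L
  if (any(sh)) out[sh] <- k[sh] / om * X1[sh] * X[tb$idx2[sh]]
  hm <- kd == 4L
  out[hm] <- k[hm] / om * X1[hm] * (X1[hm] - 1)
  th <- kd == 5L
  out[th] <- k[th] / om^2 * X1[th] * (X1[th] - 1) * (X1[th] - 2)
  pmax(out, 0)
}

# Jacobian of the intensive rates: J x n matrix d a~_j / d x_i.
.propensity_jacobian <- function(net, x) {
  tb <- net$tables
  k <- .rates(net)
  J <- length(k)
  n <- length(x)
  out <- matrix(0, J, n)
  for (j in seq_len(J)) {
    kd <- tb$kind[j]
    if (kd == 1L) next
    i1 <- tb$idx1[j]
    if (kd == 2L) {
      out[j, i1] <- k[j]
    } else if (kd == 3L) {
      i2 <- tb$idx2[j]
      out[j, i1] <- out[j, i1] + k[j] * x[i2]
      out[j, i2] <- out[j, i2] + k[j] * x[i1]
    } else if (kd == 4L) {
      out[j, i1] <- 2 * k[j] * x[i1]
    } else {
      out[j, i1] <- 3 * k[j] * x[i1]^2
    }
  }
  out
}

#' Analytic Jacobian of the deterministic vector field
#' @inheritParams scaled_propensities
#' @return `n x n` matrix `d b_i / d x_j`.
#' @export
ode_jacobian <- function(net, x) {
  net$tables$stoich %*% .propensity_jacobian(net, x)
}

.check_state <- function(net, x) {
  n <- nrow(net$species)
  if (length(x) != n) {
    stop("state has length ", length(x), " but the network has ", n, " species")
  }
  if (any(x < 0)) stop("negative state entries are outside the model domain")
  invisible(TRUE)
}

#' Lumped birth/death rates of a one-species network
#'
#' For a network with a single dynamic species, sums the propensities of all
#' channels that increase (birth) or decrease (death) the count by one unit at
#' each requested copy number. Used by the exact mean-first-passage oracle.
#'
#' @param net A one-species [reaction_network()].
#' @param size A [system_size()].
#' @param counts Integer vector of copy numbers.
#' @return A tibble with columns `count`, `birth`, `death`.
#' @export
birth_death_rates <- function(net, size, counts) {
  if (nrow(net$species) != 1L) stop("birth_death_rates needs a 1-species network")
  nu <- drop(net$tables$stoich)
  if (any(abs(nu) != 1L)) stop("all reactions must change the count by +/-1")
  purrr::map_dfr(counts, function(n) {
    a <- propensities(net, n, size)
    tibble::tibble(count = n,
                   birth = sum(a[nu > 0]),
                   death = sum(a[nu < 0]))
  })
}
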