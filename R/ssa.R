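# Exact stochastic simulation, first-passage times and the exact
# birth-death mean-first-passage oracle.

#' Simulate one exact SSA trajectory
#'
#' Gillespie's direct method: exponential waiting time at the total
#' propensity, categorical channel choice. Runs until `t_max`, or until the
#' output species count first reaches `stop_count` (recording that time as
#' the first-passage time), or until `max_events`. If every propensity
#' vanishes the trajectory freezes until `t_max` (not an error).
#'
#' @param net A [reaction_network()].
#' @param size A [system_size()].
#' @param X0 Initial integer count vector (defaults to the network initial
#'   state converted to counts).
#' @param t_max Simulation horizon (> 0, model time units).
#' @param seed Integer seed; the trajectory is reproducible from it.
#' @param stop_count Optional threshold on the output species count.
#' @param record Keep the full event history? Set `FALSE` for first-passage
#'   work to save memory.
#' @param max_events Hard cap on the number of reaction events.
#' @return An object of class `ssa_trajectory`: list with `times`, `states`
#'   (event-indexed matrix, if recorded), `t_end`, `fpt`, `terminated_by`
#'   (`"t_max"`, `"threshold"` or `"max_events"`), `seed`, `final_state`.
#' @export
ssa_run <- function(net, size, X0 = NULL, t_max, seed = 1L,
                    stop_count = NULL, record = TRUE, max_events = 5e8) {
  stopifnot(inherits(size, "system_size"), t_max > 0)
  if (is.null(X0)) X0 <- initial_state(net, size)
  .check_state(net, X0)
  if (any(X0 != round(X0))) stop("X0 must be integer counts")
  tb <- net$tables
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  res <- ssa_run_cpp(tb$stoich, tb$kind,
                     pmax(tb$idx1 - 1L, 0L), pmax(tb$idx2 - 1L, 0L),
                     .rates(net), size$omega, as.numeric(X0), t_max,
                     tb$output_index - 1L,
                     if (is.null(stop_count)) -1 else as.numeric(stop_count),
                     record, as.integer(max_events))
  if (record) colnames(res$states) <- net$species$name
  structure(c(res, list(seed = as.integer(seed), net_species = net$species$name)),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("<ssa_trajectory> %s events, t_end = %.4g, terminated by %s%s\n",
              format(x$n_events, big.mark = ","), x$t_end, x$terminated_by,
              if (!is.na(x$fpt)) sprintf(" (FPT = %.4g)", x$fpt) else ""))
  invisible(x)
}

#' Mean first-passage time from the low state by Monte Carlo
#'
#' Starts every run at the low (living) fixed point converted to counts and
#' measures the time for the output species count to reach
#' `ceiling(threshold_fraction * high-state output count)`. Runs are seeded
#' by a counter scheme (`seed + run index`), so the ensemble is reproducible
#' and independent of execution order. Runs still below threshold at `t_max`
#' are censored: counted, excluded from the mean.
#'
#' @param net A [reaction_network()].
#' @param size A [system_size()].
#' @param input_value Control-parameter value; the deterministic system must
#'   be bistable there.
#' @param threshold_fraction Fraction of the high-state mean output count
#'   defining the passage threshold, in (0, 1].
#' @param n_runs Number of independent trajectories.
#' @param t_max Per-run horizon. Default: 100 times the deterministic transit
#'   time from just past the saddle to the threshold.
#' @param seed Master seed of the counter scheme.
#' @return An object of class `fpt_ensemble`: tibble `samples` (`run`, `fpt`,
#'   `censored`) plus `mfpt`, `sd`, `cv`, `se`, `n_censored`,
#'   `threshold_count`, `threshold_fraction`, `x_low`, `x_high`.
#' @export
estimate_mfpt <- function(net, size, input_value = NULL,
                          threshold_fraction = 0.8, n_runs = 1000L,
                          t_max = NULL, seed = 1L) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  if (!is.null(input_value)) net <- set_input(net, input_value)
  bp <- bistable_points(net)   # errors if not bistable
  out_idx <- net$tables$output_index
  X0 <- round(convert_units(bp$low, size, "to_counts"))
  threshold <- unname(ceiling(threshold_fraction * bp$high[out_idx] * size$omega))
  if (is.null(t_max)) {
    t_max <- 100 * .transit_time(net, bp, threshold / size$omega)
  }
  fpt <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    run_seed <- (as.integer(seed) + i) %% .Machine$integer.max
    r <- ssa_run(net, size, X0 = X0, t_max = t_max, seed = run_seed,
                 stop_count = threshold, record = FALSE)
    fpt[i] <- r$fpt
  }
  censored <- is.na(fpt)
  ok <- fpt[!censored]
  if (!length(ok)) warning("all runs censored at t_max; MFPT undefined")
  mfpt <- if (length(ok)) mean(ok) else NA_real_
  sdv <- if (length(ok) > 1) stats::sd(ok) else NA_real_
  structure(list(
    samples = tibble::tibble(run = seq_len(n_runs), fpt = fpt,
                             censored = censored),
    mfpt = mfpt, sd = sdv, cv = sdv / mfpt,
    se = sdv / sqrt(length(ok)),
    n_censored = sum(censored), n_runs = n_runs,
    threshold_count = threshold, threshold_fraction = threshold_fraction,
    t_max = t_max, seed = as.integer(seed),
    input_value = net$parameters[[net$input_parameter]],
    omega = size$omega,
    x_low = bp$low, x_high = bp$high), class = "fpt_ensemble")
}

#' @export
print.fpt_ensemble <- function(x, ...) {
  cat(sprintf(
    "<fpt_ensemble> %d runs (%d censored): MFPT = %.5g (se %.3g), CV = %.3g\n",
    x$n_runs, x$n_censored, x$mfpt, x$se, x$cv))
  cat(sprintf("  threshold: %d counts (%.0f%% of high state), omega = %.4g\n",
              x$threshold_count, 100 * x$threshold_fraction, x$omega))
  invisible(x)
}

# Deterministic time from just past the saddle to the threshold level of the
# output species (the transit component of a switching event).
.transit_time <- function(net, bp, threshold_conc) {
  x0 <- bp$saddle + 0.05 * (bp$high - bp$saddle)
  out_idx <- net$tables$output_index
  f <- function(t, y, parms) list(ode_rhs(net, pmax(y, 0)))
  root <- function(t, y, parms) y[out_idx] - threshold_conc
  sol <- tryCatch(
    deSolve::lsodar(y = as.numeric(x0), times = c(0, 1e6), func = f,
                    rootfunc = root, rtol = 1e-8, atol = 1e-10),
    error = function(e) NULL)
  tt <- if (!is.null(sol)) attr(sol, "troot") else numeric(0)
  if (!length(tt)) {
    # fall back to the slowest linear relaxation time at the low state
    ev <- Re(eigen(ode_jacobian(net, bp$low), only.values = TRUE)$values)
    return(10 / max(1e-12, min(abs(ev))))
  }
  tt[1]
}

#' Exact mean first-passage time of a birth-death chain
#'
#' Solves the first-step (tridiagonal) recursion for the mean time to first
#' reach `target` from `start`, with reflecting behaviour at zero — exactly,
#' with no simulation. With `u_n = T_n - T_{n+1}` the recursion is
#' `u_0 = 1/b_0`, `u_n = (1 + d_n u_{n-1}) / b_n`, and
#' `T_start = sum(u_n, n = start..target-1)`.
#'
#' @param birth,death Numeric vectors of rates indexed by copy number
#'   `0..target-1` (`birth[n+1]` is the birth rate at count `n`), or
#'   functions of the count.
#' @param start,target Integer counts, `0 <= start < target`.
#' @return Mean first-passage time (model time units).
#' @export
exact_mfpt_birth_death <- function(birth, death, start, target) {
  stopifnot(target >= start, start >= 0)
  if (target == start) return(0)
  bfun <- if (is.function(birth)) birth else function(n) birth[n + 1]
  dfun <- if (is.function(death)) death else function(n) death[n + 1]
  u <- numeric(target)
  for (n in 0:(target - 1)) {
    bn <- bfun(n); dn <- if (n == 0) 0 else dfun(n)
    if (!is.finite(bn) || bn <= 0) {
      stop("zero birth rate at count ", n, " makes the target unreachable")
    }
    u[n + 1] <- if (n == 0) 1 / bn else (1 + dn * u[n]) / bn
  }
  sum(u[(start + 1):target])
}
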