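# Fixed points of the deterministic dynamics and their classification.

#' Find and classify fixed points of the mass-action dynamics
#'
#' Multi-start damped Newton on `b(x) = 0` with an analytic Jacobian.
#' Starting points combine log-spaced rescalings of the initial state,
#' relaxation endpoints of short deterministic integrations, and seeded
#' log-uniform random states; converged roots are deduplicated and classified
#' by the real parts of the Jacobian eigenvalues (`stable`: none positive;
#' `saddle`: exactly one positive, the transition-state configuration;
#' `unstable`: more than one positive).
#'
#' @param net A [reaction_network()].
#' @param input_value Optional control-parameter value (nM); if given, the
#'   input parameter is set before solving.
#' @param n_starts Number of random starts on top of the deterministic ones.
#' @param seed Integer seed making the random starts reproducible.
#' @param tol Residual tolerance on the scaled infinity norm of `b(x)`.
#' @param dedupe_tol Relative radius below which two roots are merged.
#' @param relax Include deterministic relaxation endpoints among the starts
#'   (reliable but slower); disable when good warm starts exist.
#' @return A tibble with one row per fixed point: `input_value`, `output`
#'   (output-species level), `stability`, `leading_eigenvalue` and a
#'   list-column `state`; sorted by `output`. Zero rows (with a warning) if no
#'   root is found.
#' @export
find_fixed_points <- function(net, input_value = NULL, n_starts = 24L,
                              seed = 1L, tol = 1e-10, dedupe_tol = 1e-6,
                              relax = TRUE) {
  if (!is.null(input_value)) {
    stopifnot(input_value > 0)
    net <- set_input(net, input_value)
  }
  n <- nrow(net$species)
  x0 <- pmax(initial_state(net), 1e-6)
  scale_ref <- max(x0, 1)

  starts <- list()
  for (s in 10^seq(-2, 1, length.out = 7)) starts <- c(starts, list(x0 * s))
  # deterministic relaxation endpoints catch the stable states reliably
  if (relax) {
    for (s in c(0.05, 1, 20)) {
      starts <- c(starts, list(.relax(net, x0 * s)))
    }
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  lo <- log(pmax(x0 * 1e-3, 1e-9)); hi <- log(x0 * 50 + 1)
  for (i in seq_len(n_starts)) {
    starts <- c(starts, list(exp(lo + stats::runif(n) * (hi - lo))))
  }

  roots <- list()
  for (st in starts) {
    r <- .newton(net, st, tol = tol)
    if (is.null(r)) next
    dup <- FALSE
    for (q in roots) {
      if (max(abs(r - q)) <= dedupe_tol * max(1, max(abs(q)))) { dup <- TRUE; break }
    }
    if (!dup) roots <- c(roots, list(r))
  }
  if (!length(roots)) {
    warning("no fixed point found from any start")
    return(tibble::tibble(input_value = numeric(), output = numeric(),
                          stability = character(),
                          leading_eigenvalue = numeric(), state = list()))
  }
  out_idx <- net$tables$output_index
  iv <- net$parameters[[net$input_parameter]]
  rows <- purrr::map_dfr(roots, function(x) {
    ev <- Re(eigen(ode_jacobian(net, x), only.values = TRUE)$values)
    npos <- sum(ev > 1e-8)
    tibble::tibble(
      input_value = iv, output = unname(x[out_idx]),
      stability = if (npos == 0L) "stable" else if (npos == 1L) "saddle" else "unstable",
      leading_eigenvalue = max(ev), state = list(stats::setNames(x, net$species$name)))
  })
  dplyr::arrange(rows, .data$output)
}

# Short stiff relaxation toward an attractor; start for Newton.
.relax <- function(net, x, t_end = 500) {
  f <- function(t, y, parms) list(ode_rhs(net, pmax(y, 0)))
  jac <- function(t, y, parms) ode_jacobian(net, pmax(y, 0))
  sol <- tryCatch(
    deSolve::lsoda(y = x, times = c(0, t_end), func = f, jacfunc = jac,
                   jactype = "fullusr", rtol = 1e-8, atol = 1e-10),
    error = function(e) NULL)
  if (is.null(sol) || nrow(sol) < 2) return(x)
  pmax(as.numeric(sol[nrow(sol), -1]), 0)
}

# Damped Newton with positivity clamp; NULL on failure.
.newton <- function(net, x, tol = 1e-10, max_iter = 80L) {
  tb <- net$tables
  kr <- .rates(net)
  x <- pmax(x, 0)
  for (it in seq_len(max_iter)) {
    b <- .rhs_fast(tb, kr, x)
    res <- max(abs(b)) / max(1, max(abs(x)))
    if (res < tol) return(x)
    J <- tb$stoich %*% .propensity_jacobian(net, x)
    step <- tryCatch(solve(J, -b), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    improved <- FALSE
    bmax <- max(abs(b))
    for (k in 1:12) {
      xn <- x + lam * step
      xn[xn < 0] <- 0
      bn <- .rhs_fast(tb, kr, xn)
      if (all(is.finite(bn)) && (max(abs(bn)) < bmax || lam < 1e-3)) {
        x <- xn; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) return(NULL)
  }
  b <- .rhs_fast(tb, kr, x)
  if (max(abs(b)) / max(1, max(abs(x))) < tol * 10) x else NULL
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Low/saddle/high fixed points of a bistable system
#'
#' Convenience wrapper asserting bistability: exactly two stable points and
#' one saddle (by output-species level).
#'
#' @inheritParams find_fixed_points
#' @return A list with named states `low`, `saddle`, `high` plus the
#'   fixed-point tibble.
#' @export
bistable_points <- function(net, input_value = NULL, seed = 1L, ...) {
  fps <- find_fixed_points(net, input_value = input_value, seed = seed, ...)
  st <- fps$stability
  if (sum(st == "stable") != 2L || sum(st == "saddle") != 1L) {
    stop("system is not bistable at this input value (found ",
         sum(st == "stable"), " stable, ", sum(st == "saddle"), " saddle)")
  }
  stable <- fps[st == "stable", ]
  list(low = stable$state[[which.min(stable$output)]],
       saddle = fps$state[[which(st == "saddle")]],
       high = stable$state[[which.max(stable$output)]],
       fixed_points = fps)
}
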