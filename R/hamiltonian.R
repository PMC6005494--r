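# Jump-process Hamiltonian of the large-deviation theory and the inner
# momentum problem of the geometric minimum action method.

#' Jump-process Hamiltonian and its analytic gradients
#'
#' `H(x, p) = sum_j a~_j(x) (exp(p . nu_j) - 1)`, summed over all reactions,
#' with `a~_j` the intensive (volume-free) propensities. Identically zero at
#' `p = 0`, and its `p`-gradient there is the deterministic drift `b(x)`.
#'
#' @param net A [reaction_network()].
#' @param x Concentration vector (>= the state floor used by the path solver).
#' @param p Momentum vector, same length as `x`.
#' @return List with `value`, `grad_x`, `grad_p`.
#' @export
hamiltonian <- function(net, x, p) {
  .check_state(net, x)
  stopifnot(length(p) == length(x))
  nu <- net$tables$stoich
  pn <- drop(crossprod(nu, p))
  if (any(abs(pn) > 700)) {
    stop("momentum projection |p.nu| exceeds 700; rescale the problem ",
         "(exp would overflow)")
  }
  a <- scaled_propensities(net, x)
  e <- exp(pn)
  da <- .propensity_jacobian(net, x)
  list(value = sum(a * (e - 1)),
       grad_x = drop(crossprod(da, e - 1)),
       grad_p = drop(nu %*% (a * e)))
}

# Internal fast Hamiltonian pieces on precomputed tables.
# Returns closures evaluating H, grad_p, grad_x, hess_pp at (x, p) in model
# coordinates.
.ham_funs <- function(net) {
  nu <- net$tables$stoich
  force(net)
  list(
    eval = function(x, p) {
      a <- scaled_propensities(net, x)
      pn <- drop(crossprod(nu, p))
      pn <- pmin(pmax(pn, -700), 700)
      e <- exp(pn)
      ae <- a * e
      list(H = sum(a * (e - 1)),
           gp = drop(nu %*% ae),
           hpp = nu %*% (ae * t(nu)),
           a = a, e = e)
    },
    grad_x = function(x, p) {
      pn <- drop(crossprod(nu, p))
      pn <- pmin(pmax(pn, -700), 700)
      drop(crossprod(.propensity_jacobian(net, x), exp(pn) - 1))
    })
}

#' Local geometric cost and maximising momentum
#'
#' Solves the convex program `maximise p . y  subject to  H(x, p) <= 0`
#' (the feasible set is convex and contains `p = 0`), whose value is the
#' per-unit-length cost of moving in direction `y` against the stochastic
#' dynamics. Directions aligned with the drift cost zero; the uphill
#' maximiser sits on the `H = 0` shell and is found by a KKT Newton
#' iteration, warm-startable from a previous momentum.
#'
#' @param net A [reaction_network()].
#' @param x State (concentrations, above the state floor).
#' @param y Direction vector, `||y|| > 0`.
#' @param p_init Optional warm-start momentum.
#' @param tol Newton tolerance.
#' @return List with `p` (maximiser), `ell` (cost `p . y`, >= 0), `mu`
#'   (KKT multiplier), `converged`.
#' @export
inner_momentum <- function(net, x, y, p_init = NULL, tol = 1e-10) {
  hf <- .ham_funs(net)
  res <- .inner_momentum_impl(hf, x, y, p_init = p_init, tol = tol)
  if (!res$converged) {
    warning("inner momentum solver did not converge; returning last iterate")
  }
  res
}

# Core solver on generic Hamiltonian closures (usable under a change of
# chart). KKT system: mu * grad_p H(p) = y, H(p) = 0, mu > 0.
.inner_momentum_impl <- function(hf, x, y, p_init = NULL, tol = 1e-10,
                                 max_iter = 60L, restarts = 5L) {
  n <- length(y)
  ny <- sqrt(sum(y^2))
  if (ny <= 0) stop("direction must be nonzero")
  ev0 <- hf$eval(x, rep(0, n))
  b <- ev0$gp                      # drift
  Sig <- ev0$hpp                   # diffusion tensor at p = 0
  # Quadratic-Hamiltonian initial guess (exact for Gaussian H):
  # p0 = Sig^-1 (y/mu - b), mu = sqrt(y' Sig^-1 y / b' Sig^-1 b)
  reg <- 1e-12 * max(diag(Sig), 1)
  Sigr <- Sig + diag(reg, n)
  q <- tryCatch(solve(Sigr, y), error = function(e) NULL)
  r <- tryCatch(solve(Sigr, b), error = function(e) NULL)
  if (is.null(q) || is.null(r)) {
    return(list(p = rep(0, n), ell = 0, mu = Inf, converged = FALSE))
  }
  qy <- sum(q * y); rb <- sum(r * b)
  if (qy <= 0) return(list(p = rep(0, n), ell = 0, mu = Inf, converged = TRUE))
  if (rb <= 1e-300) rb <- 1e-300
  mu0 <- sqrt(qy / rb)
  guesses <- list()
  if (!is.null(p_init) && any(p_init != 0)) {
    guesses <- c(guesses, list(list(p = p_init, mu = mu0)))
  }
  guesses <- c(guesses, list(list(p = q / mu0 - r, mu = mu0)))

  newton_from <- function(p, mu) {
    for (it in seq_len(max_iter)) {
      ev <- hf$eval(x, p)
      F1 <- mu * ev$gp - y
      F2 <- ev$H
      err <- max(max(abs(F1)) / max(1, ny), abs(F2))
      if (err < tol) {
        ell <- sum(p * y)
        return(list(p = p, ell = max(ell, 0), mu = mu, converged = TRUE))
      }
      # Jacobian of (F1, F2) wrt (p, mu): [[mu*Hpp, gp], [gp', 0]]
      K <- rbind(cbind(mu * ev$hpp, ev$gp), c(ev$gp, 0))
      step <- tryCatch(solve(K, -c(F1, F2)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      lam <- 1
      repeat {
        pn <- p + lam * step[1:n]
        mun <- mu + lam * step[n + 1]
        if (mun > 0) {
          evn <- tryCatch(hf$eval(x, pn), error = function(e) NULL)
          if (!is.null(evn) && is.finite(evn$H)) {
            errn <- max(max(abs(mun * evn$gp - y)) / max(1, ny), abs(evn$H))
            if (errn < err || lam < 1e-4) { p <- pn; mu <- mun; break }
          }
        }
        lam <- lam / 2
        if (lam < 1e-8) return(NULL)
      }
    }
    NULL
  }

  for (g in guesses) {
    res <- newton_from(g$p, g$mu)
    if (!is.null(res)) return(res)
  }
  # random restarts around the quadratic guess
  for (k in seq_len(restarts)) {
    p0 <- (q / mu0 - r) * stats::runif(n, 0.5, 1.5)
    res <- newton_from(p0, mu0 * stats::runif(1, 0.5, 2))
    if (!is.null(res)) return(res)
  }
  list(p = q / mu0 - r, ell = max(sum((q / mu0 - r) * y), 0), mu = mu0,
       converged = FALSE)
}
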