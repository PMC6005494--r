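# Geometric minimum action method on the jump-process Hamiltonian:
# minimum-action transition paths, barrier heights, landscape profiles and
# the Arrhenius cross-check against simulated switching times.

# Chart closures: evaluate the Hamiltonian and its derivatives in either the
# model (concentration) coordinates or elementwise-log coordinates. In log
# coordinates z = log x the conjugate momentum is q = p * x, so
# H~(z,q) = H(e^z, q e^-z); derivatives follow by the chain rule.
.chart_funs <- function(net, log_space = FALSE, floor = 1e-9) {
  hf <- .ham_funs(net)
  if (!log_space) {
    list(
      log_space = FALSE, floor = floor,
      to = function(x) pmax(x, floor),
      from = function(z) z,
      mom_to_model = function(z, q) q,
      eval = function(z, q) {
        ev <- hf$eval(pmax(z, floor), q)
        list(H = ev$H, gp = ev$gp, hpp = ev$hpp)
      },
      grad_x = function(z, q) hf$grad_x(pmax(z, floor), q))
  } else {
    list(
      log_space = TRUE, floor = floor,
      to = function(x) log(pmax(x, floor)),
      from = function(z) exp(z),
      mom_to_model = function(z, q) q / exp(z),
      eval = function(z, q) {
        x <- exp(z)
        ev <- hf$eval(x, q / x)
        list(H = ev$H, gp = ev$gp / x, hpp = ev$hpp * tcrossprod(1 / x))
      },
      grad_x = function(z, q) {
        x <- exp(z); p <- q / x
        gx <- hf$grad_x(x, p)
        gp <- hf$eval(x, p)$gp
        gx * x - gp * p
      })
  }
}

# Segment costs, momenta and x-gradients of the discrete geometric action.
# Z: (N+1) x n path matrix in chart coordinates. Returns per-segment cost
# ell, momenta (rows), and dl/dx at midpoints; warm starts from `penv`.
# The batched KKT Newton lives in compiled code (src/gmam.cpp).
.segment_costs <- function(net, log_space, floor, Z, penv = NULL,
                           with_grad = TRUE) {
  tb <- net$tables
  warm <- if (!is.null(penv) && !is.null(penv$P)) penv$P else matrix(0, 0, 0)
  res <- segment_costs_cpp(tb$stoich, tb$kind,
                           pmax(tb$idx1 - 1L, 0L), pmax(tb$idx2 - 1L, 0L),
                           .rates(net), Z, log_space, floor, warm, with_grad)
  out <- list(ell = drop(res$ell), P = res$P, GL = res$GL, GR = res$GR,
              converged = res$converged)
  if (length(out$ell) == 1L) out$P <- matrix(out$P, 1L)
  if (!is.null(penv)) penv$P <- res$P
  out
}

# Maximum displacement between two paths measured normal to the current
# curve; motion along the curve is reparametrisation, not shape change.
.normal_displacement <- function(Z, Z_old) {
  N1 <- nrow(Z)
  d <- Z - Z_old
  tang <- Z[c(2:N1, N1), , drop = FALSE] - Z[c(1L, 1:(N1 - 1L)), , drop = FALSE]
  tn <- sqrt(rowSums(tang^2))
  tn[tn == 0] <- 1
  tang <- tang / tn
  along <- rowSums(d * tang)
  perp <- d - along * tang
  max(sqrt(rowSums(perp^2)))
}

# Resample a polyline to m equally spaced (arc length) rows.
.resample_path <- function(Z, m) {
  seg <- sqrt(rowSums((Z[-1L, , drop = FALSE] - Z[-nrow(Z), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= 0) return(matrix(rep(Z[1L, ], m), m, byrow = TRUE))
  s <- s / s[length(s)]
  keep <- !duplicated(s)
  out <- matrix(0, m, ncol(Z))
  for (j in seq_len(ncol(Z))) {
    out[, j] <- stats::approx(s[keep], Z[keep, j], xout = seq(0, 1, length.out = m),
                              ties = "ordered")$y
  }
  out[1L, ] <- Z[1L, ]; out[m, ] <- Z[nrow(Z), ]
  out
}

# Deterministic flowline (sign = +1) or time-reversed flowline (sign = -1)
# from `from` (displaced by eps toward `toward`) until closest approach to
# `target`. Rows of states.
.flow_segment <- function(net, from, toward, target, sign = 1) {
  w <- toward - from
  nw <- sqrt(sum(w^2))
  if (nw <= 0) return(NULL)
  w <- w / nw
  scale <- max(abs(from), 1e-6)
  y0 <- pmax(from + 1e-4 * scale * w, 0)
  f <- function(t, y, parms) list(sign * ode_rhs(net, pmax(y, 0)))
  cap <- 20 * max(abs(from), abs(target), 1)
  guard <- function(t, y, parms) max(abs(y)) - cap   # stop on blow-up
  tt <- c(0, 10^seq(-2, 5, length.out = 300))
  sol <- tryCatch(
    deSolve::lsodar(y = as.numeric(y0), times = tt, func = f,
                    rootfunc = guard, rtol = 1e-8, atol = 1e-12),
    error = function(e) NULL)
  if (is.null(sol) || nrow(sol) < 3L) return(NULL)
  flow <- sol[, -1, drop = FALSE]
  d <- sqrt(rowSums(sweep(flow, 2L, target)^2))
  flow[seq_len(which.min(d)), , drop = FALSE]
}

# Initial path through the saddle: a straight segment in the model
# (linear) coordinates from the start attractor up to the saddle — linear
# interpolation keeps all species at moderate levels even when the solver
# then works in log coordinates — followed by the deterministic flowline
# from just past the saddle down to the end state, so the zero-cost descent
# branch starts on the flow.
.saddle_flow_init <- function(net, x_start, x_end, saddle, n_points) {
  n <- length(saddle)
  n_up <- max(3L, ceiling(n_points / 2))
  up <- matrix(0, n_up, n)
  for (j in seq_len(n)) up[, j] <- seq(x_start[j], saddle[j],
                                       length.out = n_up)
  down <- .flow_segment(net, saddle, x_end, x_end, sign = 1)
  if (is.null(down) || nrow(down) < 3L) {
    n_dn <- max(3L, ceiling(n_points / 2))
    down <- matrix(0, n_dn, n)
    for (j in seq_len(n)) down[, j] <- seq(saddle[j], x_end[j],
                                           length.out = n_dn)
  }
  rbind(matrix(x_start, 1L), up, matrix(saddle, 1L), down,
        matrix(x_end, 1L))
}

# Equal-arc-length reparametrisation of the path rows (linear interpolation
# of each coordinate against normalised cumulative chord length).
.reparam <- function(Z) {
  N <- nrow(Z) - 1L
  seg <- sqrt(rowSums((Z[-1L, , drop = FALSE] - Z[-(N + 1L), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[N + 1L] <= 0) return(Z)
  s <- s / s[N + 1L]
  s_new <- seq(0, 1, length.out = N + 1L)
  out <- Z
  for (j in seq_len(ncol(Z))) {
    out[, j] <- stats::approx(s, Z[, j], xout = s_new, ties = "ordered")$y
  }
  out[1L, ] <- Z[1L, ]; out[N + 1L, ] <- Z[N + 1L, ]
  out
}

#' Minimum-action transition path by the geometric method
#'
#' Computes the quasi-potential minimiser between two fixed points. The path
#' is initialised as a straight segment in the chosen coordinates and
#' improved by alternating (a) a descent sweep of the interior points against
#' the discrete geometric action — segment costs from [inner_momentum()] with
#' envelope gradients, minimised by bounded quasi-Newton — with (b) an
#' equal-arc-length reparametrisation. Endpoints stay pinned. Convergence:
#' relative action change below `tol` and maximum point displacement below
#' `tol` times the path length between consecutive outer cycles.
#'
#' @param net A [reaction_network()].
#' @param x_start,x_end Distinct fixed points (concentration vectors).
#' @param n_points Number of path points (`N + 1` including endpoints).
#' @param tol Convergence tolerance.
#' @param max_iter Maximum outer cycles.
#' @param log_space Work in elementwise-log coordinates? Recommended when
#'   species levels span decades (the apoptosis-like fixture); off for the
#'   Schlogl-type fixtures.
#' @param floor State floor (nM) keeping propensities and logs defined.
#' @param init Optional initial path: a matrix of states (rows, model
#'   coordinates). Default: straight segment in chart coordinates.
#'   [barrier_height()] passes a saddle-through initialisation whose descent
#'   half follows the deterministic flow.
#' @return An object of class `transition_path`: tibble `points` (arc
#'   position, species columns, `segment_action`, `cumulative_action`),
#'   `momenta` matrix (model coordinates), `total_action`, `barrier` (max
#'   cumulative action), `converged`, `iterations`.
#' @export
gmam_path <- function(net, x_start, x_end, n_points = 100L, tol = 1e-4,
                      max_iter = 60L, log_space = FALSE, floor = 1e-9,
                      init = NULL) {
  n <- nrow(net$species)
  stopifnot(length(x_start) == n, length(x_end) == n)
  cf <- .chart_funs(net, log_space = log_space, floor = floor)
  z0 <- cf$to(as.numeric(x_start)); z1 <- cf$to(as.numeric(x_end))
  stopifnot(n_points >= 3L)
  N <- n_points - 1L
  if (max(abs(z1 - z0)) < 1e-12) {
    pts <- .path_tibble(net, cf, matrix(rep(z0, 2), nrow = 2, byrow = TRUE),
                        c(0, 0))
    return(structure(list(points = pts$tib, momenta = matrix(0, 1, n),
                          total_action = 0, barrier = 0, converged = TRUE,
                          iterations = 0L, log_space = log_space),
                     class = "transition_path"))
  }
  if (!is.null(init)) {
    stopifnot(is.matrix(init), ncol(init) == n)
    Zi <- t(apply(init, 1L, cf$to))
    if (n == 1L) Zi <- matrix(cf$to(init[, 1L]), ncol = 1L)
    Zi[1L, ] <- z0; Zi[nrow(Zi), ] <- z1
    Z <- .resample_path(Zi, N + 1L)
  } else {
    Z <- matrix(0, N + 1L, n)
    for (j in seq_len(n)) Z[, j] <- seq(z0[j], z1[j], length.out = N + 1L)
  }

  penv <- new.env(parent = emptyenv())
  S_prev <- Inf
  S_best <- Inf
  stall <- 0L
  converged <- FALSE
  iter <- 0L
  pathlen <- function(Z) sum(sqrt(rowSums(
    (Z[-1L, , drop = FALSE] - Z[-(N + 1L), , drop = FALSE])^2)))

  for (iter in seq_len(max_iter)) {
    Z_old <- Z
    if (iter > 1L) Z <- .reparam(Z)
    interior <- as.numeric(Z[2:N, , drop = FALSE])
    cache <- new.env(parent = emptyenv())
    eval_path <- function(par) {
      key <- paste0(format(sum(par * seq_along(par)), digits = 17), "_",
                    format(sum(par^2), digits = 17))
      if (identical(cache$key, key)) return(cache$val)
      Zi <- Z
      Zi[2:N, ] <- matrix(par, N - 1L, n)
      sc <- .segment_costs(net, log_space, floor, Zi, penv = penv)
      grad <- matrix(0, N - 1L, n)
      for (k in 2:N) {
        grad[k - 1L, ] <- sc$GR[k - 1L, ] + sc$GL[k, ]
      }
      val <- list(S = sum(sc$ell), grad = as.numeric(grad), sc = sc)
      cache$key <- key; cache$val <- val
      val
    }
    lower <- if (log_space) log(floor) else floor
    upper <- if (log_space) max(c(z0, z1)) + log(100) else Inf
    opt <- stats::optim(
      interior,
      fn = function(par) eval_path(par)$S,
      gr = function(par) eval_path(par)$grad,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = min(400L, max(60L, 2L * length(interior))),
                     factr = 1e7))
    Z[2:N, ] <- matrix(opt$par, N - 1L, n)
    S <- opt$value
    dS <- abs(S - S_prev) / max(abs(S), 1e-300)
    # displacement normal to the curve (tangential sliding is pure gauge)
    disp <- .normal_displacement(Z, Z_old) / max(pathlen(Z), 1e-300)
    S_prev <- S
    if (dS < tol && disp < tol) { converged <- TRUE; break }
    # stationarity: no action improvement beyond tol over several cycles
    # (the optimise/reparametrise alternation has a small noise floor; the
    # optimised action is the quantity that must have stabilised)
    if (!is.finite(S_best)) {
      S_best <- S
    } else if (S < S_best - tol * max(abs(S_best), 1e-300)) {
      S_best <- min(S_best, S); stall <- 0L
    } else {
      S_best <- min(S_best, S); stall <- stall + 1L
      if (stall >= 5L) { converged <- TRUE; break }
    }
  }

  sc <- .segment_costs(net, log_space, floor, Z, penv = penv, with_grad = FALSE)
  if (any(sc$ell < -1e-8)) {
    stop("internal consistency error: negative segment action ",
         min(sc$ell))
  }
  seg <- pmax(sc$ell, 0)
  cum <- c(0, cumsum(seg))
  pts <- .path_tibble(net, cf, Z, cum)
  mom <- matrix(0, N + 1L, n)
  for (i in seq_len(N)) {
    m <- (Z[i, ] + Z[i + 1L, ]) / 2
    mom[i, ] <- cf$mom_to_model(m, sc$P[i, ])
  }
  mom[N + 1L, ] <- mom[N, ]
  colnames(mom) <- net$species$name
  structure(list(points = pts$tib, momenta = mom,
                 total_action = cum[N + 1L],
                 barrier = max(cum), converged = converged,
                 iterations = iter, log_space = log_space),
            class = "transition_path")
}

.path_tibble <- function(net, cf, Z, cum) {
  if (ncol(Z) == 1L) {
    X <- matrix(cf$from(Z[, 1L]), ncol = 1L)
  } else {
    X <- t(apply(Z, 1L, cf$from))
  }
  colnames(X) <- net$species$name
  seg <- sqrt(rowSums((Z[-1L, , drop = FALSE] -
                         Z[-nrow(Z), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  if (max(arc) > 0) arc <- arc / max(arc)
  tib <- dplyr::bind_cols(
    tibble::tibble(arc_position = arc),
    tibble::as_tibble(X),
    tibble::tibble(cumulative_action = cum,
                   segment_action = c(0, diff(cum))))
  list(tib = tib)
}

#' @export
print.transition_path <- function(x, ...) {
  cat(sprintf(
    "<transition_path> %d points, total action %.6g, barrier %.6g (%s, %d outer cycles)\n",
    nrow(x$points), x$total_action, x$barrier,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Closed-form one-dimensional quasi-potential
#'
#' For a one-dimensional jump process with lumped intensive birth rate
#' `birth(x)` and death rate `death(x)`, the quasi-potential from `a` up to
#' `b` is the quadrature `integral of log(death(x)/birth(x)) dx` — the
#' analytic oracle against which the geometric path solver is validated.
#'
#' @param birth,death Vectorisable positive rate functions of concentration.
#' @param a,b Integration limits (uphill from `a` to `b`).
#' @return The quasi-potential increment (intensive action units).
#' @export
closed_form_quasipotential_1d <- function(birth, death, a, b) {
  bmin <- min(birth(seq(min(a, b), max(a, b), length.out = 201)))
  if (!is.finite(bmin) || bmin <= 0) {
    stop("birth rate vanishes on the integration interval")
  }
  stats::integrate(function(x) log(death(x) / birth(x)), a, b,
                   rel.tol = 1e-10)$value
}

#' Quasi-potential barrier height at a given input value
#'
#' Runs [gmam_path()] from the low to the high state and reports the barrier
#' (maximum cumulative action along the path, attained at the saddle
#' crossing), the cumulative action at the path point nearest the
#' independently computed saddle, and the full path.
#'
#' @param net A [reaction_network()].
#' @param input_value Control-parameter value (deterministically bistable).
#' @param n_points,tol,max_iter,log_space,floor Passed to [gmam_path()].
#' @return List with `barrier`, `action_at_saddle`, `total_action`,
#'   `converged`, `path`, `points` (the bistable fixed points).
#' @export
barrier_height <- function(net, input_value = NULL, n_points = 100L,
                           tol = 1e-4, max_iter = 60L, log_space = FALSE,
                           floor = 1e-9) {
  if (!is.null(input_value)) net <- set_input(net, input_value)
  bp <- bistable_points(net)
  init <- .saddle_flow_init(net, bp$low, bp$high, bp$saddle, n_points)
  path <- gmam_path(net, bp$low, bp$high, n_points = n_points, tol = tol,
                    max_iter = max_iter, log_space = log_space, floor = floor,
                    init = init)
  sp <- net$species$name
  X <- as.matrix(path$points[, sp, drop = FALSE])
  d <- sqrt(rowSums((sweep(X, 2L, bp$saddle))^2))
  i_sad <- which.min(d)
  list(barrier = path$barrier,
       action_at_saddle = path$points$cumulative_action[i_sad],
       total_action = path$total_action,
       converged = path$converged,
       input_value = net$parameters[[net$input_parameter]],
       path = path, points = bp)
}

#' Two-well quasi-potential profile along the output coordinate
#'
#' Concatenates the uphill branch of the low-to-high minimum-action path
#' (cumulative action from the living state up to the saddle) with the
#' reverse high-to-low path (giving the death-state well, matched at the
#' saddle), projected on the output species.
#'
#' @inheritParams barrier_height
#' @param log_coordinate Return the output coordinate on a log10 scale?
#' @return An object of class `landscape_profile`: tibble with `coordinate`,
#'   `action`, `branch` (`"living"` / `"death"`), plus `barrier` and
#'   `well_depths`.
#' @export
landscape_profile <- function(net, input_value = NULL, log_coordinate = TRUE,
                              n_points = 100L, tol = 1e-4, max_iter = 60L,
                              log_space = log_coordinate, floor = 1e-9) {
  if (!is.null(input_value)) net <- set_input(net, input_value)
  bp <- bistable_points(net)
  fwd <- gmam_path(net, bp$low, bp$high, n_points = n_points, tol = tol,
                   max_iter = max_iter, log_space = log_space, floor = floor,
                   init = .saddle_flow_init(net, bp$low, bp$high, bp$saddle,
                                            n_points))
  rev <- gmam_path(net, bp$high, bp$low, n_points = n_points, tol = tol,
                   max_iter = max_iter, log_space = log_space, floor = floor,
                   init = .saddle_flow_init(net, bp$high, bp$low, bp$saddle,
                                            n_points))
  out <- net$output_species
  dS_f <- fwd$barrier
  dS_r <- rev$barrier
  cum_f <- fwd$points$cumulative_action
  i_sad_f <- which.max(cum_f > dS_f - 1e-12)   # first point attaining barrier
  left <- tibble::tibble(coordinate = fwd$points[[out]][1:i_sad_f],
                         action = cum_f[1:i_sad_f], branch = "living")
  cum_r <- rev$points$cumulative_action
  i_sad_r <- which.max(cum_r > dS_r - 1e-12)
  right <- tibble::tibble(
    coordinate = rev$points[[out]][1:i_sad_r],
    action = dS_f - dS_r + cum_r[1:i_sad_r],
    branch = "death")
  prof <- dplyr::bind_rows(left, right[rev(seq_len(nrow(right))), ])
  if (log_coordinate) prof$coordinate <- log10(pmax(prof$coordinate, floor))
  structure(list(profile = prof, barrier = dS_f,
                 well_depths = c(living = dS_f, death = dS_r),
                 input_value = net$parameters[[net$input_parameter]],
                 log_coordinate = log_coordinate,
                 converged = fwd$converged && rev$converged),
            class = "landscape_profile")
}

#' @export
print.landscape_profile <- function(x, ...) {
  cat(sprintf(
    "<landscape_profile> barrier %.6g; well depths: living %.6g, death %.6g\n",
    x$barrier, x$well_depths[["living"]], x$well_depths[["death"]]))
  invisible(x)
}

#' Arrhenius estimate of the barrier from switching times
#'
#' Estimates the mean first-passage time at several system sizes and
#' regresses `log(MFPT)` on `omega`; by the large-deviation (Arrhenius)
#' relation the slope estimates the quasi-potential barrier height. Sizes
#' whose runs are all censored are dropped with a warning; at least three
#' must remain.
#'
#' @param net A [reaction_network()].
#' @param sizes List of [system_size()] objects (or numeric omegas), >= 3.
#' @param input_value Control-parameter value (bistable).
#' @param n_runs Runs per size.
#' @param seed Master seed (each size uses `seed + 1000 * size index`).
#' @param threshold_fraction,t_max Passed to [estimate_mfpt()].
#' @return An object of class `arrhenius_fit`: tibble `by_size` (`omega`,
#'   `mfpt`, `se`, `n_censored`), `slope` (barrier estimate), `intercept`,
#'   `fit` (the `lm` object).
#' @export
arrhenius_estimate <- function(net, sizes, input_value = NULL, n_runs = 400L,
                               seed = 1L, threshold_fraction = 0.8,
                               t_max = NULL) {
  if (length(sizes) < 3L) stop("need at least 3 system sizes")
  sizes <- lapply(sizes, function(s) {
    if (inherits(s, "system_size")) s else system_size(omega = s)
  })
  rows <- purrr::imap_dfr(sizes, function(s, i) {
    # per-size seed keyed to the size itself, so the estimate for a given
    # omega does not depend on the order the sizes are listed in
    ens <- estimate_mfpt(net, s, input_value = input_value,
                         threshold_fraction = threshold_fraction,
                         n_runs = n_runs, t_max = t_max,
                         seed = (as.integer(seed) +
                                   1000L * as.integer(round(s$omega))) %%
                           .Machine$integer.max)
    tibble::tibble(omega = s$omega, mfpt = ens$mfpt, se = ens$se,
                   n_censored = ens$n_censored, n_runs = ens$n_runs)
  })
  bad <- is.na(rows$mfpt)
  if (any(bad)) {
    warning("dropping ", sum(bad), " fully censored size(s)")
    rows <- rows[!bad, ]
  }
  if (nrow(rows) < 3L) stop("fewer than 3 sizes with defined MFPT")
  fit <- stats::lm(log(mfpt) ~ omega, data = rows)
  structure(list(by_size = rows,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> slope (barrier estimate) = %.5g over %d sizes\n",
    x$slope, nrow(x$by_size)))
  invisible(x)
}
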