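# Geometric minimum-action paths, barriers, landscapes, Arrhenius fits.

test_that("a path between identical endpoints is trivial", {
  net <- make_schlogl()
  p <- gmam_path(net, 1.3, 1.3)
  expect_equal(p$total_action, 0)
  expect_equal(p$barrier, 0)
  expect_true(p$converged)
})

test_that("Schlögl uphill action matches the quadrature oracle", {
  net <- make_schlogl()
  bd <- schlogl_rates(net)
  roots <- schlogl_roots_oracle(net)
  oracle <- closed_form_quasipotential_1d(bd$birth, bd$death,
                                          roots[1], roots[2])
  bh <- barrier_height(net)
  expect_true(bh$converged)
  expect_equal(bh$barrier, oracle, tolerance = 1e-3)
  # the barrier is attained at the saddle crossing
  expect_equal(bh$action_at_saddle, bh$barrier, tolerance = 1e-6)
})

test_that("the reversed path integrates the complementary interval", {
  net <- make_schlogl()
  bd <- schlogl_rates(net)
  roots <- schlogl_roots_oracle(net)
  # exit cost from the high state: integral of log(birth/death) reversed
  oracle_rev <- -closed_form_quasipotential_1d(bd$birth, bd$death,
                                               roots[2], roots[3])
  p_rev <- gmam_path(net, roots[3], roots[1])
  expect_equal(p_rev$barrier, oracle_rev, tolerance = 1e-3)
  p_fwd <- gmam_path(net, roots[1], roots[3])
  expect_gt(abs(p_fwd$barrier - p_rev$barrier), 0.05)  # asymmetric landscape
})

test_that("closed-form quadrature handles the trivial cases", {
  expect_equal(closed_form_quasipotential_1d(function(x) 1 + 0 * x,
                                             function(x) 1 + 0 * x, 0, 5), 0)
  expect_equal(closed_form_quasipotential_1d(function(x) 1 + 0 * x,
                                             function(x) exp(1) + 0 * x,
                                             0, 1), 1, tolerance = 1e-9)
  expect_error(closed_form_quasipotential_1d(function(x) 0 * x,
                                             function(x) 1 + 0 * x, 0, 1),
               "vanishes")
})

test_that("segment actions are non-negative and accumulate to the barrier", {
  net <- make_toggle2()
  bp <- bistable_points(net)
  p <- gmam_path(net, bp$low, bp$high, n_points = 60)
  expect_true(all(p$points$segment_action >= -1e-8))
  cum <- p$points$cumulative_action
  expect_equal(max(cum), p$barrier)
  i_max <- which.max(cum)
  expect_true(all(diff(cum[1:i_max]) >= -1e-10))
  expect_lte(p$barrier, p$total_action + 1e-8)
})

test_that("the toggle barrier is stable under path refinement", {
  net <- make_toggle2()
  b1 <- barrier_height(net, n_points = 60)
  b2 <- barrier_height(net, n_points = 120)
  expect_true(b1$converged && b2$converged)
  expect_lt(abs(b2$barrier - b1$barrier) / b1$barrier, 0.005)
})

test_that("toggle barrier agrees with an independent graph-path oracle", {
  # Independent route: restrict to paths that are graphs Y(X) over a fixed
  # X grid from the low state to the saddle, evaluate segment costs with the
  # R-side KKT solver, and minimise over the Y knots with Nelder-Mead.
  net <- make_toggle2()
  bp <- bistable_points(net)
  nx <- 30
  xs <- seq(bp$low[["X"]], bp$saddle[["X"]], length.out = nx)
  hf <- switchscape:::.ham_funs(net)
  path_action <- function(yk) {
    kx <- seq(xs[1], xs[nx], length.out = 8)
    Y <- spline(kx, c(bp$low[["Y"]], yk, bp$saddle[["Y"]]), xout = xs,
                method = "natural")$y
    S <- 0
    for (i in 1:(nx - 1)) {
      m <- c((xs[i] + xs[i + 1]) / 2, (Y[i] + Y[i + 1]) / 2)
      y <- c(xs[i + 1] - xs[i], Y[i + 1] - Y[i])
      S <- S + switchscape:::.inner_momentum_impl(hf, m, y)$ell
    }
    S
  }
  y0 <- seq(bp$low[["Y"]], bp$saddle[["Y"]], length.out = 8)[2:7]
  opt <- optim(y0, path_action, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-10))
  opt <- optim(opt$par, path_action, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-10))
  bh <- barrier_height(net, n_points = 120)
  expect_equal(bh$barrier, opt$value, tolerance = 0.02)
})

test_that("barrier vanishes at the fold and decreases towards it", {
  net <- make_schlogl()
  k <- net$parameters
  fold <- schlogl_upper_fold_oracle(k[["k1"]], k[["k2"]], k[["k4"]])
  b_near <- barrier_height(net, input_value = fold * 0.999, n_points = 60)
  b_far <- barrier_height(net, input_value = 4.3, n_points = 60)
  expect_lt(b_near$barrier, 1e-3 * b_far$barrier)
})

test_that("the landscape profile has two wells separated by the saddle", {
  net <- make_schlogl()
  lp <- landscape_profile(net, log_coordinate = FALSE, log_space = FALSE)
  prof <- lp$profile
  expect_equal(prof$action[1], 0)
  expect_equal(prof$action[nrow(prof)],
               lp$well_depths[["living"]] - lp$well_depths[["death"]],
               tolerance = 1e-6)
  # interior maximum sits at the saddle concentration
  roots <- schlogl_roots_oracle(net)
  expect_equal(prof$coordinate[which.max(prof$action)], roots[2],
               tolerance = 0.05)
  # endpoints are the two minima of their branches
  expect_true(all(prof$action <= max(prof$action) + 1e-12))
  expect_s3_class(autoplot(lp), "ggplot")
})

test_that("Arrhenius regression wiring: slope, drop policy, shuffling", {
  net <- make_schlogl()
  sizes <- c(10, 12, 14, 16)
  fit <- arrhenius_estimate(net, sizes, n_runs = 120, seed = 5, t_max = 3000)
  expect_equal(nrow(fit$by_size), 4L)
  manual <- lm(log(mfpt) ~ omega, data = fit$by_size)
  expect_equal(fit$slope, unname(coef(manual)[2]))
  expect_gt(fit$slope, 0)
  # shuffling the size order leaves the regression unchanged
  fit2 <- arrhenius_estimate(net, sizes[c(3, 1, 4, 2)], n_runs = 120,
                             seed = 5, t_max = 3000)
  expect_equal(fit2$slope, fit$slope)
  expect_error(arrhenius_estimate(net, c(10, 12), n_runs = 10, seed = 1),
               "at least 3")
})
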