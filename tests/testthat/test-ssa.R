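# Exact stochastic simulation and first-passage machinery.

test_that("constant production is a Poisson process", {
  net <- birth_only_net(k = 2)
  sz <- system_size(omega = 10)   # rate omega*k = 20 per time unit
  t_end <- 3
  counts <- vapply(1:1000, function(i) {
    ssa_run(net, sz, X0 = 0, t_max = t_end, seed = i, record = FALSE)$final_state
  }, numeric(1))
  lambda <- sz$omega * 2 * t_end
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # variance equals the mean for a Poisson count (loose factor-level check)
  expect_gt(var(counts), 0.8 * lambda)
  expect_lt(var(counts), 1.25 * lambda)
})

test_that("pure death absorbs at zero and freezes until t_max", {
  net <- death_only_net()
  sz <- system_size(omega = 1)
  tr <- ssa_run(net, sz, X0 = 5, t_max = 50, seed = 4)
  expect_equal(unname(tr$final_state), 0)
  expect_equal(tr$terminated_by, "t_max")
  expect_equal(tr$t_end, 50)
  expect_equal(nrow(tr$states), 6L)   # exactly five deaths recorded
})

test_that("birth-death settles at the stationary mean count", {
  net <- birth_death_net(kb = 1.2, kd = 0.6)
  sz <- system_size(volume = 100)
  finals <- vapply(1:200, function(i) {
    ssa_run(net, sz, X0 = 0, t_max = 30, seed = 100 + i,
            record = FALSE)$final_state
  }, numeric(1))
  expected <- sz$omega * 1.2 / 0.6   # Poisson stationary mean
  se <- sqrt(expected / length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("trajectories are reproducible from the seed", {
  net <- make_schlogl()
  sz <- system_size(omega = 15)
  a <- ssa_run(net, sz, t_max = 5, seed = 11)
  b <- ssa_run(net, sz, t_max = 5, seed = 11)
  expect_identical(a$times, b$times)
  expect_identical(a$states, b$states)
  c <- ssa_run(net, sz, t_max = 5, seed = 12)
  expect_false(identical(a$times, c$times))
})

test_that("estimate_mfpt is reproducible and censors at t_max", {
  net <- make_schlogl()
  sz <- system_size(omega = 15)
  e1 <- estimate_mfpt(net, sz, input_value = 5.5, n_runs = 50, t_max = 200,
                      seed = 9)
  e2 <- estimate_mfpt(net, sz, input_value = 5.5, n_runs = 50, t_max = 200,
                      seed = 9)
  expect_identical(e1$samples$fpt, e2$samples$fpt)
  expect_equal(e1$mfpt, mean(e1$samples$fpt[!e1$samples$censored]))
  expect_equal(e1$cv, e1$sd / e1$mfpt)
  # threshold is the ceiling of the fraction times the high-state count
  bp <- bistable_points(set_input(net, 5.5))
  expect_equal(e1$threshold_count,
               ceiling(0.8 * bp$high[["X"]] * sz$omega))
  # a tiny horizon censors everything and flags the ensemble
  expect_warning(
    ec <- estimate_mfpt(net, sz, input_value = 4.3, n_runs = 5, t_max = 1e-4,
                        seed = 2),
    "censored")
  expect_true(is.na(ec$mfpt))
  expect_equal(ec$n_censored, 5L)
  # non-bistable input errors
  expect_error(estimate_mfpt(net, sz, input_value = 10, n_runs = 5,
                             t_max = 1, seed = 1), "not bistable")
})

test_that("a threshold below the initial state gives zero passage times", {
  net <- make_schlogl()
  sz <- system_size(omega = 15)
  e <- estimate_mfpt(net, sz, input_value = 5, threshold_fraction = 0.01,
                     n_runs = 10, t_max = 10, seed = 3)
  expect_true(all(e$samples$fpt == 0))
  expect_equal(e$mfpt, 0)
})

test_that("MFPT shortens as the pump approaches the fold (paired seeds)", {
  net <- make_schlogl()
  sz <- system_size(omega = 15)
  mf <- vapply(c(5.0, 5.6, 6.2), function(k3) {
    estimate_mfpt(net, sz, input_value = k3, n_runs = 150, t_max = 2000,
                  seed = 77)$mfpt
  }, numeric(1))
  expect_true(all(diff(mf) < 0))
})

test_that("exact birth-death passage times obey the closed forms", {
  expect_equal(exact_mfpt_birth_death(function(n) 2, function(n) 1, 3, 3), 0)
  # pure birth chain: sum of exponential waiting means
  expect_equal(exact_mfpt_birth_death(function(n) n + 1, function(n) 0, 0, 5),
               sum(1 / (1:5)))
  expect_error(exact_mfpt_birth_death(function(n) 0, function(n) 1, 0, 3),
               "unreachable")
  # M/M/1-like chain cross-checked against direct linear solve
  birth <- function(n) 3
  death <- function(n) 0.5 * n
  target <- 12
  A <- matrix(0, target, target)
  rhs <- rep(-1, target)
  for (nn in 0:(target - 1)) {
    i <- nn + 1
    b <- birth(nn); d <- if (nn == 0) 0 else death(nn)
    A[i, i] <- -(b + d)
    if (i > 1) A[i, i - 1] <- d
    if (i < target) A[i, i + 1] <- b
  }
  Tvec <- solve(A, rhs)
  expect_equal(exact_mfpt_birth_death(birth, death, 2, target), Tvec[3],
               tolerance = 1e-10)
})

test_that("SSA mean first-passage agrees with the exact chain at small size", {
  net <- make_schlogl()
  sz <- system_size(omega = 12)
  ens <- estimate_mfpt(net, sz, n_runs = 400, t_max = 5000, seed = 21)
  bd <- schlogl_rates(net)
  k <- net$parameters
  birth <- function(n) sz$omega * k[["k3"]] + k[["k1"]] / sz$omega * n * (n - 1)
  death <- function(n) k[["k4"]] * n +
    k[["k2"]] / sz$omega^2 * n * (n - 1) * (n - 2)
  exact <- exact_mfpt_birth_death(birth, death,
                                  start = round(0.45 * sz$omega),
                                  target = ens$threshold_count)
  expect_lt(abs(ens$mfpt - exact), 3 * ens$se)
})

test_that("birth_death_rates lumps one-species channels correctly", {
  net <- make_schlogl()
  sz <- system_size(omega = 10)
  tb <- birth_death_rates(net, sz, counts = c(0, 5))
  k <- net$parameters
  expect_equal(tb$birth[1], sz$omega * k[["k3"]])
  expect_equal(tb$death[1], 0)
  expect_equal(tb$birth[2], sz$omega * k[["k3"]] + k[["k1"]] / 10 * 5 * 4)
  expect_equal(tb$death[2], k[["k4"]] * 5 + k[["k2"]] / 100 * 5 * 4 * 3)
  expect_error(birth_death_rates(make_toggle2(), sz, 1), "1-species")
})
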