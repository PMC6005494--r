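# Local spectra, Sobol indices, Spearman comparisons.

test_that("local spectrum reproduces analytic percent responses", {
  net <- make_schlogl()
  # linear functional of one parameter: +2% in, +2.000% out
  sp_lin <- local_spectrum(net, output_fn = function(n) 5 * n$parameters[["k1"]],
                           delta = 0.02)
  e <- sp_lin$entries[sp_lin$entries$parameter == "k1", ]
  expect_equal(e$pct_up, 2, tolerance = 1e-9)
  expect_equal(e$pct_down, -2, tolerance = 1e-9)
  expect_equal(e$oncogenic_direction, "up")
  # reciprocal functional: +2% in, -1.9608% out; decrease is oncogenic
  sp_inv <- local_spectrum(net, output_fn = function(n) 3 / n$parameters[["k1"]],
                           delta = 0.02)
  e2 <- sp_inv$entries[sp_inv$entries$parameter == "k1", ]
  expect_equal(e2$pct_up, 100 * (1 / 1.02 - 1), tolerance = 1e-9)
  expect_equal(e2$pct_down, 100 * (1 / 0.98 - 1), tolerance = 1e-9)
  expect_equal(e2$oncogenic_direction, "down")
  expect_equal(e2$magnitude, abs(100 * (1 / 0.98 - 1)), tolerance = 1e-9)
})

test_that("fold-location spectrum matches the discriminant oracle responses", {
  net <- make_schlogl()
  sp <- local_spectrum(net, "sn_location", delta = 0.02, seed = 2)
  k <- net$parameters
  base <- schlogl_upper_fold_oracle(k[["k1"]], k[["k2"]], k[["k4"]])
  expect_equal(sp$baseline, base, tolerance = 1e-4)
  # input parameter is the condition axis, not a spectrum entry
  expect_false("k3" %in% sp$entries$parameter)
  for (pn in c("k1", "k2", "k4")) {
    kk <- k
    kk[pn] <- k[pn] * 1.02
    oracle_up <- 100 * (schlogl_upper_fold_oracle(kk[["k1"]], kk[["k2"]],
                                                  kk[["k4"]]) - base) / base
    got <- sp$entries$pct_up[sp$entries$parameter == pn]
    expect_equal(got, oracle_up, tolerance = 1e-3)
  }
  # near-linear regime: increase and decrease responses mirror each other
  ok <- sp$entries
  expect_true(all(abs(ok$pct_up + ok$pct_down) <=
                    0.2 * pmax(abs(ok$pct_up), abs(ok$pct_down))))
})

test_that("Sobol total effects recover the additive-variance decomposition", {
  f <- function(U) U[, 1] + 2 * U[, 2]
  res <- sobol_indices(f, d = 2, n_base = 512, seed = 4)
  e <- res$entries
  expect_lt(abs(e$total_effect[1] - 0.2), 0.05)
  expect_lt(abs(e$total_effect[2] - 0.8), 0.05)
  # bootstrap CIs bracket the analytic indices
  expect_true(e$total_lo[1] <= 0.2 && 0.2 <= e$total_hi[1])
  expect_true(e$total_lo[2] <= 0.8 && 0.8 <= e$total_hi[2])
  # additive function: first-order indices sum to one within CI noise
  expect_lt(abs(sum(e$first_order) - 1), 0.1)
})

test_that("a single active input takes all the variance", {
  f <- function(U) sin(2 * pi * U[, 2])
  res <- sobol_indices(f, d = 3, n_base = 512, seed = 9)
  e <- res$entries
  expect_lt(abs(e$total_effect[2] - 1), 0.1)
  expect_lt(max(abs(e$total_effect[c(1, 3)])), 0.05)
})

test_that("Jansen estimates agree with a brute-force double loop", {
  # non-additive test function with interactions
  f_row <- function(u) u[1] * exp(u[2]) + 0.5 * u[3]^2
  f <- function(U) apply(U, 1, f_row)
  res <- sobol_indices(f, d = 3, n_base = 1024, seed = 11)
  # double-loop Monte Carlo oracle for the total effect:
  # ST_i = E[Var(Y | X_~i)] / Var(Y)
  set.seed(99)
  n_out <- 400; n_in <- 400
  Vtot <- var(f(matrix(runif(3 * 20000), ncol = 3)))
  st_oracle <- vapply(1:3, function(i) {
    evar <- mean(vapply(seq_len(n_out), function(r) {
      base <- runif(3)
      U <- matrix(rep(base, each = n_in), ncol = 3)
      U[, i] <- runif(n_in)
      var(f(U))
    }, numeric(1)))
    evar / Vtot
  }, numeric(1))
  expect_true(all(abs(res$entries$total_effect - st_oracle) < 0.05))
})

test_that("Sobol estimates are stable under seed change and in range", {
  f <- function(U) U[, 1] + 2 * U[, 2]
  a <- sobol_indices(f, d = 2, n_base = 256, seed = 1)
  b <- sobol_indices(f, d = 2, n_base = 256, seed = 2)
  expect_true(all(abs(a$entries$total_effect - b$entries$total_effect) < 0.08))
  expect_true(all(a$entries$total_effect > -0.05 &
                    a$entries$total_effect < 1.05))
})

test_that("rejection sampling reports draw counts and aborts when hopeless", {
  f <- function(U) ifelse(U[, 1] > 0.5, NA_real_, U[, 1] + U[, 2])
  res <- sobol_indices(f, d = 2, n_base = 64, seed = 3)
  expect_gt(res$n_drawn, res$n_base)   # rejections happened
  expect_equal(res$n_accepted, 64L)
  f_bad <- function(U) rep(NA_real_, nrow(U))
  expect_error(sobol_indices(f_bad, d = 2, n_base = 16, seed = 1,
                             max_reject = 200), "acceptance")
})

test_that("spearman_rho reproduces rank-formula values and validates keys", {
  a <- c(p1 = 1, p2 = 2, p3 = 3, p4 = 4)
  expect_equal(spearman_rho(a, a)$rho, 1)
  expect_equal(spearman_rho(a, a[rev(names(a))])$rho, 1)  # key-aligned
  b <- c(p1 = 4, p2 = 3, p3 = 2, p4 = 1)
  expect_equal(spearman_rho(a, b)$rho, -1)
  # one tied pair: average ranks, hand-computed correlation
  x <- c(p1 = 1, p2 = 2, p3 = 2, p4 = 4)
  y <- c(p1 = 1, p2 = 2, p3 = 3, p4 = 4)
  rx <- rank(x); ry <- rank(y)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y)$rho, hand, tolerance = 1e-12)
  expect_error(spearman_rho(a, c(p1 = 1, p2 = 2, p9 = 3)),
               "differ")
  expect_error(spearman_rho(a[1:2], b[1:2]), "at least 3")
})

test_that("compare_spectra builds a symmetric unit-diagonal table", {
  s1 <- c(a = 3, b = 2, c = 1)
  s2 <- c(a = 2.5, b = 2.2, c = 0.5)
  s3 <- c(a = 1, b = 2, c = 3)
  cmp <- compare_spectra(list(x = s1, y = s2, z = s3))
  M <- attr(cmp, "matrix")
  expect_equal(diag(M), c(x = 1, y = 1, z = 1))
  expect_equal(M, t(M))
  expect_equal(M["x", "z"], -1)
  f <- withr::local_tempfile(fileext = ".csv")
  compare_spectra(list(x = s1, y = s2), out_csv = f)
  expect_true(file.exists(f))
})

test_that("MFPT spectra are robust to the passage threshold choice", {
  net <- make_schlogl()
  sz <- system_size(omega = 15)
  spectra <- lapply(c(0.5, 0.8, 0.9), function(thr) {
    sp <- local_spectrum(net, "mfpt",
                         condition = list(size = sz, input_value = 5.3,
                                          threshold_fraction = thr,
                                          n_runs = 300, t_max = 2000),
                         seed = 31)
    stats::setNames(sp$entries$magnitude, sp$entries$parameter)
  })
  expect_gte(spearman_rho(spectra[[1]], spectra[[2]])$rho, 0.95)
  expect_gte(spearman_rho(spectra[[2]], spectra[[3]])$rho, 0.95)
})
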