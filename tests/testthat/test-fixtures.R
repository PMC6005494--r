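# Packaged model fixtures and perturbation families.

test_that("Schlögl defaults give three positive deterministic roots", {
  net <- make_schlogl()
  roots <- schlogl_roots_oracle(net)
  expect_equal(length(roots), 3L)
  expect_equal(roots, c(0.45, 2.2, 4.3), tolerance = 1e-9)
  kinds <- vapply(net$reactions, `[[`, character(1), "kind")
  expect_setequal(kinds, c("second_homo", "third_homo", "zeroth", "first"))
  expect_equal(net$input_parameter, "k3")
})

test_that("disabling the autocatalysis collapses the switch", {
  expect_warning(net <- make_schlogl(list(k1 = 1e-9)), "not bistable")
  expect_equal(nrow(find_fixed_points(net)), 1L)
})

test_that("the pump parameter has exactly two folds", {
  net <- make_schlogl()
  k <- net$parameters
  # discriminant oracle: folds at g(x) for the two critical points of the
  # decreasing part of the cubic
  disc <- 4 * k[["k1"]]^2 - 12 * k[["k2"]] * k[["k4"]]
  xc <- (2 * k[["k1"]] + c(-1, 1) * sqrt(disc)) / (6 * k[["k2"]])
  folds <- sort(k[["k2"]] * xc^3 - k[["k1"]] * xc^2 + k[["k4"]] * xc)
  counts <- vapply(c(folds[1] * 0.9, mean(folds), folds[2] * 1.1),
                   function(v) nrow(find_fixed_points(net, input_value = v)),
                   integer(1))
  expect_equal(counts, c(1L, 3L, 1L))
})

test_that("the two-species shuttle motif inherits the Schlögl fixed points", {
  tg <- make_toggle2()
  fps <- find_fixed_points(tg)
  expect_equal(nrow(fps), 3L)
  expect_equal(fps$stability, c("stable", "saddle", "stable"))
  expect_equal(fps$output, c(0.45, 2.2, 4.3), tolerance = 1e-6)
  # Y equilibrates to ks1/ks2 times X at every fixed point
  for (st in fps$state) {
    expect_equal(st[["Y"]], st[["X"]] * tg$parameters[["ks1"]] /
                   tg$parameters[["ks2"]], tolerance = 1e-6)
  }
  # decoupling limit: vanishing shuttle recovers the marginal dynamics
  tg0 <- make_toggle2(list(ks1 = 1e-10, ks2 = 1e-10))
  x <- c(1.5, 7)
  expect_equal(ode_rhs(tg0, x)[["X"]],
               ode_rhs(make_schlogl(), 1.5)[["X"]], tolerance = 1e-8)
})

test_that("perturbation families enumerate 2 per kinetic parameter", {
  net <- make_schlogl()
  ps <- perturbation_set(net, delta = 0.02)
  expect_equal(nrow(ps), 6L)   # 3 non-input parameters, up and down
  for (i in seq_len(nrow(ps))) {
    changed <- ps$network[[i]]$parameters / net$parameters
    expect_equal(sort(unique(round(changed, 10))),
                 sort(unique(c(1, ps$factor[i]))))
    expect_equal(sum(changed != 1), 1L)
    expect_equal(names(which(changed != 1)), ps$parameter[i])
  }
  ps_all <- perturbation_set(net, delta = 0.02, include_input = TRUE)
  expect_equal(nrow(ps_all), 8L)
  # apoptosis fixture: 2 x kinetic parameter count
  apo <- load_apoptosis_fixture()
  expect_equal(nrow(perturbation_set(apo, 0.02)),
               2L * (length(apo$parameters) - 1L))
  expect_error(perturbation_set(net, delta = 0.5))
})

test_that("the apoptosis-like fixture has the documented structure", {
  net <- load_apoptosis_fixture()
  expect_equal(nrow(net$species), 20L)
  expect_equal(length(net$reactions), 53L)
  expect_equal(net$input_parameter, "cas8")
  expect_equal(net$output_species, "Bax4M")
  kinds <- vapply(net$reactions, `[[`, character(1), "kind")
  # only the three rate-law types of the pathway model
  expect_setequal(unique(kinds), c("zeroth", "first", "second_hetero",
                                   "second_homo"))
  # the initiator caspase acts as a constant-concentration modifier
  mods <- vapply(net$reactions, `[[`, character(1), "modifier")
  expect_true("cas8" %in% mods)
  # packaged JSON is exactly the programmatic construction
  expect_equal(make_apoptosis_synthetic()$parameters, net$parameters)
  expect_equal(make_apoptosis_synthetic()$species, net$species)
})

test_that("fixture generation is deterministic", {
  a <- make_toggle2(); b <- make_toggle2()
  expect_identical(a$parameters, b$parameters)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_model(a, f1); save_model(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})
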