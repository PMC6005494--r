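# Network construction, validation, serialisation and unit conversion.

test_that("minimal one-species zeroth-order model loads from JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "species": [{"name": "X", "initial_nM": 0, "output": true}],
    "reactions": [{"id": "pump", "reactants": {}, "products": {"X": 1},
                   "rate": "k", "modifier": null}],
    "parameters": {"k": 1.5},
    "input_parameter": "k"
  }', f)
  net <- load_model(f)
  expect_equal(nrow(net$species), 1L)
  expect_equal(length(net$reactions), 1L)
  expect_equal(net$reactions[[1]]$kind, "zeroth")
  expect_equal(net$output_species, "X")
})

test_that("schema violations give descriptive errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "species": [{"name": "X", "initial_nM": 0, "output": true}],
    "reactions": [{"id": "r", "reactants": {"X": 1}, "products": {},
                   "rate": "k_undeclared", "modifier": null}],
    "parameters": {"k": 1},
    "input_parameter": "k"
  }', f)
  expect_error(load_model(f), "k_undeclared")
  writeLines('{"species": []}', f)
  expect_error(load_model(f), "reactions")
  expect_error(load_model(tempfile()), "not found")
})

test_that("network validation rejects bad inputs", {
  sp <- tibble::tibble(name = "X", initial_nM = 1, output = TRUE)
  rx <- list(reaction("r", c(X = 1), NULL, rate = "k"))
  expect_error(reaction_network(sp, rx, c(k = -1), "k"), "positive")
  expect_error(reaction_network(sp, rx, c(k = 1), "nope"), "input_parameter")
  expect_error(reaction_network(rbind(sp, sp), rx, c(k = 1), "k"), "unique")
  expect_error(
    reaction_network(sp, list(reaction("r", c(Y = 1), NULL, rate = "k")),
                     c(k = 1), "k"),
    "undeclared species")
  # order-3 heterogeneous reactant sets are not a supported rate law
  expect_error(reaction("bad", c(X = 2, Y = 1), NULL, rate = "k"),
               "not supported")
})

test_that("save_model/load_model round-trips byte-identically", {
  for (net in list(make_schlogl(), make_toggle2(), random_net(seed = 7))) {
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    save_model(net, f1)
    net2 <- load_model(f1)
    save_model(net2, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(net2$parameters, net$parameters)
    expect_equal(net2$species, net$species)
  }
})

test_that("unit conversion follows Avogadro arithmetic and inverts", {
  sz <- system_size(volume = 100)
  expect_equal(sz$omega, 60.2214, tolerance = 1e-6)
  expect_equal(convert_units(1, sz, "to_counts"), 60.2214, tolerance = 1e-6)
  expect_equal(convert_units(0, sz, "to_counts"), 0)
  expect_equal(convert_units(0, sz, "to_concentration"), 0)
  x <- c(0.3, 1.7, 12)
  back <- convert_units(convert_units(x, sz, "to_counts"), sz,
                        "to_concentration")
  expect_equal(back, x)
  # integer rounding loses at most half a molecule
  rounded <- convert_units(x, sz, "to_counts", integer_counts = TRUE)
  expect_true(all(abs(rounded / sz$omega - x) <= 0.5 / sz$omega + 1e-12))
  expect_error(convert_units(-1, sz), "negative")
  expect_equal(system_size(omega = 20)$omega, 20)
})

test_that("deterministic field equals stoichiometry times intensive rates", {
  for (seed in 1:5) {
    net <- random_net(n_species = 4, n_reactions = 10, seed = seed)
    for (rep in 1:3) {
      x <- runif(4, 0, 5)
      expect_equal(ode_rhs(net, x),
                   drop(net$tables$stoich %*% scaled_propensities(net, x)),
                   tolerance = 1e-12)
    }
  }
})

test_that("count propensities approach intensive rates in the volume limit", {
  net <- random_net(n_species = 3, n_reactions = 8, seed = 3)
  x <- c(1.3, 0.7, 2.1)
  atil <- scaled_propensities(net, x)
  err <- sapply(c(1e2, 1e4, 1e6), function(om) {
    sz <- system_size(omega = om)
    X <- round(x * om)
    max(abs(propensities(net, X, sz) / om - scaled_propensities(net, X / om)))
  })
  expect_lt(err[1], 0.2)
  # error shrinks roughly like 1/omega
  expect_lt(err[2], err[1] / 50)
  expect_lt(err[3], err[2] / 50)
})

test_that("propensity formulas match the volume-scaled convention", {
  sz <- system_size(volume = 100)
  # zeroth order: a = omega * k
  expect_equal(propensities(birth_only_net(k = 2), 0, sz), 2 * sz$omega)
  # first order with modifier: a = cas8 * k1 * X_Bid
  net <- bid_cleavage_net(cas8 = 3, k1 = 0.5)
  expect_equal(propensities(net, c(7, 0), sz), 3 * 0.5 * 7)
  expect_equal(ode_rhs(net, c(2, 0)),
               c(Bid = -3 * 0.5 * 2, tBid = 3 * 0.5 * 2))
  # homodimerisation: a = k/omega * X (X - 1), no 1/2 factor
  dim_net <- reaction_network(
    species = tibble::tibble(name = c("X", "X2"), initial_nM = c(2, 0),
                             output = c(FALSE, TRUE)),
    reactions = list(reaction("dim", c(X = 2), c(X2 = 1), rate = "k")),
    parameters = c(k = 0.4), input_parameter = "k")
  expect_equal(propensities(dim_net, c(10, 0), sz), 0.4 / sz$omega * 10 * 9)
  # mass-action dimerisation field: dX/dt = -2 k x^2, dX2/dt = +k x^2
  expect_equal(ode_rhs(dim_net, c(3, 0)),
               c(X = -2 * 0.4 * 9, X2 = 0.4 * 9))
  # absorbing empty state without zeroth-order channels
  expect_equal(propensities(dim_net, c(0, 0), sz), 0)
  expect_error(propensities(dim_net, c(-1, 0), sz), "negative")
})

test_that("Schlögl intensive rates match the hand expansion", {
  net <- make_schlogl()
  k <- net$parameters
  x <- 1.7
  expect_equal(scaled_propensities(net, x),
               c(k[["k1"]] * x^2, k[["k2"]] * x^3, k[["k3"]], k[["k4"]] * x),
               tolerance = 1e-12)
  # trimolecular extension: propensity V^-2 k X(X-1)(X-2)
  sz <- system_size(omega = 10)
  a <- propensities(net, 5, sz)
  expect_equal(a[2], k[["k2"]] / 100 * 5 * 4 * 3)
})

test_that("set_parameters and set_input update and validate", {
  net <- make_schlogl()
  expect_equal(set_input(net, 5)$parameters[["k3"]], 5)
  expect_equal(set_parameters(net, k1 = 7)$parameters[["k1"]], 7)
  expect_error(set_parameters(net, bogus = 1), "unknown")
  expect_error(set_parameters(net, k1 = -2), "positive")
})
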