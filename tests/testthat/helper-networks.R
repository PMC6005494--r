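# Small test networks and oracles shared across test files.

# One species, constant production: 0 -> X at rate k.
birth_only_net <- function(k = 2) {
  reaction_network(
    species = tibble::tibble(name = "X", initial_nM = 0, output = TRUE),
    reactions = list(reaction("pump", NULL, c(X = 1), rate = "k")),
    parameters = c(k = k), input_parameter = "k")
}

# Birth-death: 0 -> X (kb), X -> 0 (kd); fixed point at kb/kd.
birth_death_net <- function(kb = 2, kd = 1) {
  reaction_network(
    species = tibble::tibble(name = "X", initial_nM = 0, output = TRUE),
    reactions = list(reaction("birth", NULL, c(X = 1), rate = "kb"),
                     reaction("death", c(X = 1), NULL, rate = "kd")),
    parameters = c(kb = kb, kd = kd), input_parameter = "kb")
}

# Pure death from X0.
death_only_net <- function(kd = 1) {
  reaction_network(
    species = tibble::tibble(name = "X", initial_nM = 5, output = TRUE),
    reactions = list(reaction("death", c(X = 1), NULL, rate = "kd")),
    parameters = c(kd = kd), input_parameter = "kd")
}

# Modifier example: Bid -> tBid catalysed by a constant cas8 level.
bid_cleavage_net <- function(cas8 = 3, k1 = 0.5) {
  reaction_network(
    species = tibble::tibble(name = c("Bid", "tBid"),
                             initial_nM = c(10, 0),
                             output = c(FALSE, TRUE)),
    reactions = list(
      reaction("cleave", c(Bid = 1), c(tBid = 1), rate = "k1",
               modifier = "cas8")),
    parameters = c(k1 = k1, cas8 = cas8), input_parameter = "cas8")
}

# Random mass-action network for property tests: n species, all four core
# rate-law kinds represented, positive random rates.
random_net <- function(n_species = 3, n_reactions = 8, seed = 1) {
  set.seed(seed)
  sp <- paste0("S", seq_len(n_species))
  rxn <- list()
  pars <- c()
  for (j in seq_len(n_reactions)) {
    kind <- sample(c("zeroth", "first", "second_hetero", "second_homo"), 1)
    kn <- paste0("k", j)
    pars[kn] <- stats::runif(1, 0.1, 3)
    reac <- switch(kind,
      zeroth = NULL,
      first = stats::setNames(1L, sample(sp, 1)),
      second_hetero = stats::setNames(c(1L, 1L), sample(sp, 2)),
      second_homo = stats::setNames(2L, sample(sp, 1)))
    prod <- stats::setNames(1L, sample(sp, 1))
    rxn[[j]] <- reaction(paste0("r", j), reac, prod, rate = kn)
  }
  reaction_network(
    species = tibble::tibble(name = sp,
                             initial_nM = stats::runif(n_species, 0.5, 5),
                             output = seq_len(n_species) == 1L),
    reactions = rxn, parameters = pars, input_parameter = "k1")
}

# Schlögl oracles -------------------------------------------------------------

schlogl_rates <- function(net) {
  k <- net$parameters
  list(birth = function(x) k[["k1"]] * x^2 + k[["k3"]],
       death = function(x) k[["k2"]] * x^3 + k[["k4"]] * x)
}

# Real positive roots of the Schlögl rate cubic via companion-matrix
# root-finding (polyroot), independent of the package's Newton solver.
schlogl_roots_oracle <- function(net) {
  k <- net$parameters
  cf <- c(k[["k3"]], -k[["k4"]], k[["k1"]], -k[["k2"]])  # ascending powers
  z <- polyroot(cf)
  r <- Re(z[abs(Im(z)) < 1e-8])
  sort(r[r > 0])
}

# Upper fold of the pump parameter from the cubic critical points:
# k3 at which the low root and the middle root merge.
schlogl_upper_fold_oracle <- function(k1, k2, k4) {
  disc <- 4 * k1^2 - 12 * k2 * k4
  if (disc <= 0) return(NA_real_)
  x_minus <- (2 * k1 - sqrt(disc)) / (6 * k2)
  k2 * x_minus^3 - k1 * x_minus^2 + k4 * x_minus
}

# Zoomed dense grid search for the inner momentum problem (2-D only).
grid_inner_oracle <- function(net, x, y, r0 = 6, stages = 4, K = 61) {
  ctr <- c(0, 0); r <- r0; best <- 0
  for (s in seq_len(stages)) {
    g1 <- seq(ctr[1] - r, ctr[1] + r, length.out = K)
    g2 <- seq(ctr[2] - r, ctr[2] + r, length.out = K)
    best <- -Inf; at <- ctr
    for (p1 in g1) {
      H <- vapply(g2, function(p2) hamiltonian(net, x, c(p1, p2))$value, 0)
      v <- p1 * y[1] + g2 * y[2]
      ok <- H <= 0
      if (any(ok)) {
        vv <- ifelse(ok, v, -Inf)
        j <- which.max(vv)
        if (vv[j] > best) { best <- vv[j]; at <- c(p1, g2[j]) }
      }
    }
    ctr <- at; r <- r / (K / 6)
  }
  max(best, 0)
}
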