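# Packaged bistable model fixtures. All are generated in code; the JSON files
# under inst/extdata are written by these constructors.

#' The Schlogl trimolecular network
#'
#' One dynamic species with autocatalysis `2X -> 3X` (rate `k1`), its
#' trimolecular reverse `3X -> 2X` (`k2`, the declared third-order rate-law
#' extension), a pump `0 -> X` (`k3`, the control parameter) and linear decay
#' `X -> 0` (`k4`). The committed defaults place the deterministic fixed
#' points at concentrations 0.45, 2.2 and 4.3 (outer two stable, middle one a
#' saddle), giving a bistable pump window of roughly `k3` in (1.06, 6.58).
#'
#' @param overrides Named list/vector overriding any of `k1, k2, k3, k4`.
#' @return A [reaction_network()]; if the overrides destroy bistability the
#'   network is still returned, with a warning.
#' @export
make_schlogl <- function(overrides = NULL) {
  pars <- c(k1 = 6.95, k2 = 1, k3 = 4.257, k4 = 12.385)
  pars <- .apply_overrides(pars, overrides)
  net <- reaction_network(
    species = tibble::tibble(name = "X", initial_nM = 0.45, output = TRUE),
    reactions = list(
      reaction("autocatalysis", c(X = 2), c(X = 3), rate = "k1"),
      reaction("reverse", c(X = 3), c(X = 2), rate = "k2"),
      reaction("pump", NULL, c(X = 1), rate = "k3"),
      reaction("decay", c(X = 1), NULL, rate = "k4")),
    parameters = pars, input_parameter = "k3")
  .warn_if_monostable(net, "make_schlogl")
  net
}

#' Two-species bistable shuttle motif
#'
#' The Schlogl species `X` augmented with a first-order shuttle `X <-> Y`
#' (rates `ks1`, `ks2`). The shuttle flux cancels at steady state, so the
#' fixed-point structure of `X` is inherited from the Schlogl core while the
#' transition path becomes genuinely two-dimensional. Setting the shuttle
#' rates to zero recovers the marginal Schlogl dynamics.
#'
#' @param overrides Named list/vector overriding any of
#'   `k1, k2, k3, k4, ks1, ks2`.
#' @return A [reaction_network()].
#' @export
make_toggle2 <- function(overrides = NULL) {
  pars <- c(k1 = 6.95, k2 = 1, k3 = 4.257, k4 = 12.385, ks1 = 2, ks2 = 3)
  pars <- .apply_overrides(pars, overrides)
  net <- reaction_network(
    species = tibble::tibble(name = c("X", "Y"),
                             initial_nM = c(0.45, 0.45 * pars[["ks1"]] / pars[["ks2"]]),
                             output = c(TRUE, FALSE)),
    reactions = list(
      reaction("autocatalysis", c(X = 2), c(X = 3), rate = "k1"),
      reaction("reverse", c(X = 3), c(X = 2), rate = "k2"),
      reaction("pump", NULL, c(X = 1), rate = "k3"),
      reaction("decay", c(X = 1), NULL, rate = "k4"),
      reaction("shuttle_out", c(X = 1), c(Y = 1), rate = "ks1"),
      reaction("shuttle_back", c(Y = 1), c(X = 1), rate = "ks2")),
    parameters = pars, input_parameter = "k3")
  .warn_if_monostable(net, "make_toggle2")
  net
}

.apply_overrides <- function(pars, overrides) {
  if (is.null(overrides) || !length(overrides)) return(pars)
  overrides <- unlist(overrides)
  unknown <- setdiff(names(overrides), names(pars))
  if (length(unknown)) {
    stop("unknown override parameters: ", paste(unknown, collapse = ", "))
  }
  pars[names(overrides)] <- overrides
  pars
}

.warn_if_monostable <- function(net, who) {
  fps <- tryCatch(find_fixed_points(net, seed = 1L),
                  warning = function(w) NULL)
  n_stable <- if (is.null(fps)) 0L else sum(fps$stability == "stable")
  if (n_stable < 2L) {
    warning(who, ": network is not bistable at these parameter values")
  }
  invisible(NULL)
}

#' Family of singly-perturbed networks
#'
#' Enumerates `2 * n_parameters` variants of `net`, each with exactly one
#' parameter multiplied by `1 + delta` or `1 - delta`, in stable order
#' (parameter order, increase before decrease). The designated input
#' parameter is skipped: it is the condition axis, not a kinetic constant.
#'
#' @param net A [reaction_network()].
#' @param delta Perturbation fraction in (0, 0.2].
#' @param include_input Also perturb the input parameter? Default `FALSE`.
#' @return A tibble with columns `parameter`, `direction` (`"up"`/`"down"`),
#'   `factor` and a list-column `network`.
#' @export
perturbation_set <- function(net, delta = 0.02, include_input = FALSE) {
  stopifnot(delta > 0, delta <= 0.2)
  pars <- names(net$parameters)
  if (!include_input) pars <- setdiff(pars, net$input_parameter)
  grid <- tidyr::expand_grid(parameter = pars, direction = c("up", "down"))
  grid$factor <- ifelse(grid$direction == "up", 1 + delta, 1 - delta)
  grid$network <- purrr::pmap(grid, function(parameter, direction, factor) {
    upd <- stats::setNames(net$parameters[[parameter]] * factor, parameter)
    set_parameters(net, upd)
  })
  grid
}

#' Path to a packaged model fixture
#' @param name Fixture file name, e.g. `"schlogl.json"`.
#' @return Absolute path.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "switchscape")
  if (!nzchar(p)) stop("packaged fixture not found: ", name)
  p
}

#' Load the synthetic mitochondrial-apoptosis-like switch
#'
#' A 20-species, 53-reaction mass-action network emulating the structure of
#' the simplified mitochondrial apoptosis pathway: an initiator caspase level
#' (`cas8`, the designated input parameter, acting as a constant-concentration
#' modifier) truncates Bid; tBid activates Bax to the mitochondrial outer
#' membrane where activated Bax recruits further Bax (positive feedback),
#' dimerises and tetramerises into the pore-forming output species `Bax4M`;
#' Bcl2 sequesters both tBid and membrane Bax; a linear downstream release
#' cascade (Smac/cytochrome-c/caspase) hangs off the pore without feeding
#' back. Only zeroth-, first- and second-order channels are used.
#'
#' This fixture is a synthetic reconstruction: its topology and species/
#' reaction counts follow the published structural description of the
#' pathway, but the rate constants were designed in-package (and verified
#' bistable in a `cas8` window at build time), not transcribed from any
#' published supplement.
#'
#' @return A [reaction_network()] with 20 species and 53 reactions, bistable
#'   in a `cas8` window, output species `Bax4M`.
#' @export
load_apoptosis_fixture <- function() {
  load_model(fixture_path("apoptosis_synthetic.json"))
}

#' Construct the synthetic apoptosis-like switch in code
#'
#' Programmatic source of the packaged `apoptosis_synthetic.json` fixture;
#' see [load_apoptosis_fixture()] for the biology it emulates.
#'
#' @param overrides Named list/vector overriding any default parameter.
#' @return A [reaction_network()].
#' @export
make_apoptosis_synthetic <- function(overrides = NULL) {
  species <- tibble::tibble(
    name = c("Bid", "tBid", "Bax", "BaxM", "Bax2M", "Bax4M",
             "Bcl2", "tBidBcl2", "BaxMBcl2", "Bcl2M",
             "Smac", "SmacR", "CytC", "CytCR", "Apaf", "Apop",
             "Casp9", "Casp3", "XIAP", "SmacXIAP"),
    initial_nM = c(40, 0, 80, 0, 0, 0,
                   20, 0, 0, 0,
                   50, 0, 50, 0, 30, 0,
                   20, 0, 30, 0),
    output = c(rep(FALSE, 5), TRUE, rep(FALSE, 14)))

  pars <- c(
    cas8 = 10,                       # input: initiator caspase level (nM)
    bid_pro = 2, bid_deg = 0.05,
    k1 = 0.005,                      # Bid -> tBid, catalysed by cas8
    tbid_deg = 0.1, tbid_rev = 0.01,
    bax_pro = 10, bax_deg = 0.05,
    k_act = 0.002,                   # tBid + Bax -> tBid + BaxM
    k_auto = 0.0065,                 # BaxM + Bax -> 2 BaxM (positive feedback)
    kf12 = 0.25,                     # BaxM -> Bax (membrane separation)
    baxm_deg = 0.05,
    k12 = 0.02, km12 = 0.02,         # 2 BaxM <-> Bax2M
    k13 = 0.02, km13 = 0.02,         # 2 Bax2M <-> Bax4M
    bax2_deg = 0.05, bax4_deg = 0.05,
    bcl2_pro = 3, bcl2_deg = 0.02,
    b_on = 0.05, b_off = 0.002,      # Bcl2 + tBid <-> tBidBcl2
    bb_on = 0.05, bb_off = 0.002,    # Bcl2 + BaxM <-> BaxMBcl2
    cplx_deg = 0.02,
    bcl2_onM = 0.05, bcl2_offM = 0.05,  # Bcl2 <-> Bcl2M translocation
    bcl2m_deg = 0.02,
    smac_pro = 1, smac_deg = 0.02, k_rel_s = 0.001, smacr_deg = 0.05,
    smac_rec = 0.01,
    cytc_pro = 1, cytc_deg = 0.02, k_rel_c = 0.001, cytcr_deg = 0.05,
    cytc_rec = 0.01,
    apaf_pro = 0.6, apaf_deg = 0.02, k_apop = 0.002, apop_deg = 0.05,
    apop_rev = 0.01,
    c9_pro = 0.4, c9_deg = 0.02, k_c9 = 0.002,
    k_c3 = 0.01, c3_deg = 0.05,
    xiap_pro = 0.6, xiap_deg = 0.02, kx_on = 0.01, kx_off = 0.001,
    sx_deg = 0.02)
  pars <- .apply_overrides(pars, overrides)

  rxn <- list(
    # Bid / tBid module
    reaction("bid_pro", NULL, c(Bid = 1), rate = "bid_pro"),
    reaction("bid_deg", c(Bid = 1), NULL, rate = "bid_deg"),
    reaction("bid_cleave", c(Bid = 1), c(tBid = 1), rate = "k1", modifier = "cas8"),
    reaction("tbid_deg", c(tBid = 1), NULL, rate = "tbid_deg"),
    # Bax core with membrane recruitment feedback
    reaction("bax_pro", NULL, c(Bax = 1), rate = "bax_pro"),
    reaction("bax_deg", c(Bax = 1), NULL, rate = "bax_deg"),
    reaction("bax_act", c(tBid = 1, Bax = 1), c(tBid = 1, BaxM = 1), rate = "k_act"),
    reaction("bax_auto", c(BaxM = 1, Bax = 1), c(BaxM = 2), rate = "k_auto"),
    reaction("baxm_off", c(BaxM = 1), c(Bax = 1), rate = "kf12"),
    reaction("baxm_deg", c(BaxM = 1), NULL, rate = "baxm_deg"),
    reaction("dimerise", c(BaxM = 2), c(Bax2M = 1), rate = "k12"),
    reaction("undimerise", c(Bax2M = 1), c(BaxM = 2), rate = "km12"),
    reaction("tetramerise", c(Bax2M = 2), c(Bax4M = 1), rate = "k13"),
    reaction("untetramerise", c(Bax4M = 1), c(Bax2M = 2), rate = "km13"),
    reaction("bax2_deg", c(Bax2M = 1), NULL, rate = "bax2_deg"),
    reaction("bax4_deg", c(Bax4M = 1), NULL, rate = "bax4_deg"),
    # Bcl2 buffering
    reaction("bcl2_pro", NULL, c(Bcl2 = 1), rate = "bcl2_pro"),
    reaction("bcl2_deg", c(Bcl2 = 1), NULL, rate = "bcl2_deg"),
    reaction("tbid_bind", c(Bcl2 = 1, tBid = 1), c(tBidBcl2 = 1), rate = "b_on"),
    reaction("tbid_unbind", c(tBidBcl2 = 1), c(Bcl2 = 1, tBid = 1), rate = "b_off"),
    reaction("tbidbcl2_deg", c(tBidBcl2 = 1), NULL, rate = "cplx_deg"),
    reaction("baxm_bind", c(Bcl2 = 1, BaxM = 1), c(BaxMBcl2 = 1), rate = "bb_on"),
    reaction("baxm_unbind", c(BaxMBcl2 = 1), c(Bcl2 = 1, BaxM = 1), rate = "bb_off"),
    reaction("baxmbcl2_deg", c(BaxMBcl2 = 1), NULL, rate = "cplx_deg"),
    reaction("bcl2_onM", c(Bcl2 = 1), c(Bcl2M = 1), rate = "bcl2_onM"),
    reaction("bcl2_offM", c(Bcl2M = 1), c(Bcl2 = 1), rate = "bcl2_offM"),
    reaction("bcl2m_deg", c(Bcl2M = 1), NULL, rate = "bcl2m_deg"),
    # downstream release cascade (no feedback onto the core)
    reaction("smac_pro", NULL, c(Smac = 1), rate = "smac_pro"),
    reaction("smac_deg", c(Smac = 1), NULL, rate = "smac_deg"),
    reaction("smac_rel", c(Smac = 1, Bax4M = 1), c(SmacR = 1, Bax4M = 1), rate = "k_rel_s"),
    reaction("smacr_deg", c(SmacR = 1), NULL, rate = "smacr_deg"),
    reaction("cytc_pro", NULL, c(CytC = 1), rate = "cytc_pro"),
    reaction("cytc_deg", c(CytC = 1), NULL, rate = "cytc_deg"),
    reaction("cytc_rel", c(CytC = 1, Bax4M = 1), c(CytCR = 1, Bax4M = 1), rate = "k_rel_c"),
    reaction("cytcr_deg", c(CytCR = 1), NULL, rate = "cytcr_deg"),
    reaction("apaf_pro", NULL, c(Apaf = 1), rate = "apaf_pro"),
    reaction("apaf_deg", c(Apaf = 1), NULL, rate = "apaf_deg"),
    reaction("apop_form", c(CytCR = 1, Apaf = 1), c(Apop = 1), rate = "k_apop"),
    reaction("apop_deg", c(Apop = 1), NULL, rate = "apop_deg"),
    reaction("c9_pro", NULL, c(Casp9 = 1), rate = "c9_pro"),
    reaction("c9_deg", c(Casp9 = 1), NULL, rate = "c9_deg"),
    reaction("c9_act", c(Casp9 = 1, Apop = 1), c(Casp3 = 1, Apop = 1), rate = "k_c9"),
    reaction("c3_deg", c(Casp3 = 1), NULL, rate = "c3_deg"),
    reaction("xiap_pro", NULL, c(XIAP = 1), rate = "xiap_pro"),
    reaction("xiap_deg", c(XIAP = 1), NULL, rate = "xiap_deg"),
    reaction("smac_xiap", c(SmacR = 1, XIAP = 1), c(SmacXIAP = 1), rate = "kx_on"),
    reaction("smac_xiap_off", c(SmacXIAP = 1), c(SmacR = 1, XIAP = 1), rate = "kx_off"),
    reaction("sx_deg", c(SmacXIAP = 1), NULL, rate = "sx_deg"),
    # recycling closures
    reaction("tbid_to_bid", c(tBid = 1), c(Bid = 1), rate = "tbid_rev"),
    reaction("smacr_recapture", c(SmacR = 1), c(Smac = 1), rate = "smac_rec"),
    reaction("cytcr_recapture", c(CytCR = 1), c(CytC = 1), rate = "cytc_rec"),
    reaction("apop_disassemble", c(Apop = 1), c(Apaf = 1), rate = "apop_rev"),
    reaction("c3_inhibition", c(Casp3 = 1, XIAP = 1), c(XIAP = 1), rate = "k_c3"))

  reaction_network(species, rxn, pars, input_parameter = "cas8")
}
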