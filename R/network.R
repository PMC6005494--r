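# Mass-action reaction networks: construction, validation, (de)serialisation.

#' Molecules per nanomolar per cubic micrometre
#'
#' Avogadro's number times 1e-9 (mol/L per nM) times 1e-15 (L per um^3).
#' @keywords internal
#' @noRd
.MOLEC_PER_NM_UM3 <- 6.02214e23 * 1e-9 * 1e-15

#' System size: volume and count-concentration scale
#'
#' Links molecule counts to concentrations. `omega` is the number of molecules
#' corresponding to 1 nM at the given volume; the large-deviation small
#' parameter is `1/omega`.
#'
#' @param volume Cell (compartment) volume in cubic micrometres. Ignored if
#'   `omega` is given.
#' @param omega Molecules per nM. If supplied, `volume` is back-computed.
#' @return An object of class `system_size` with fields `volume` and `omega`.
#' @examples
#' system_size(volume = 100)   # omega ~ 60.22 molecules per nM
#' @export
system_size <- function(volume = NULL, omega = NULL) {
  if (is.null(volume) && is.null(omega)) {
    stop("supply `volume` (um^3) or `omega` (molecules per nM)")
  }
  if (is.null(omega)) {
    stopifnot(is.numeric(volume), length(volume) == 1L, volume > 0)
    omega <- volume * .MOLEC_PER_NM_UM3
  } else {
    stopifnot(is.numeric(omega), length(omega) == 1L, omega > 0)
    volume <- omega / .MOLEC_PER_NM_UM3
  }
  structure(list(volume = volume, omega = omega), class = "system_size")
}

#' @export
print.system_size <- function(x, ...) {
  cat(sprintf("<system_size> volume = %.6g um^3, omega = %.6g molecules/nM\n",
              x$volume, x$omega))
  invisible(x)
}

#' Convert between molecule counts and concentrations
#'
#' `counts = concentration * omega`. Counts are rounded to the nearest integer
#' only when `integer_counts = TRUE` (an integer state is required); the
#' inverse map is exact.
#'
#' @param value Non-negative numeric vector.
#' @param size A [system_size()].
#' @param direction `"to_counts"` or `"to_concentration"`.
#' @param integer_counts Round counts to nearest integer? Default `FALSE`.
#' @return Numeric vector on the requested scale.
#' @export
convert_units <- function(value, size,
                          direction = c("to_counts", "to_concentration"),
                          integer_counts = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(size, "system_size"))
  if (any(value < 0)) stop("negative quantities have no physical meaning here")
  if (direction == "to_counts") {
    out <- value * size$omega
    if (integer_counts) out <- round(out)
    out
  } else {
    value / size$omega
  }
}

.KINDS <- c("zeroth", "first", "second_hetero", "second_homo", "third_homo")

# Derive the rate-law kind from the reactant multiset.
.reaction_kind <- function(reactants) {
  tot <- sum(reactants)
  if (tot == 0L) return("zeroth")
  if (tot == 1L) return("first")
  if (tot == 2L) {
    return(if (length(reactants) == 1L) "second_homo" else "second_hetero")
  }
  if (tot == 3L && length(reactants) == 1L) return("third_homo")
  stop("reactant stoichiometry not supported: total order ", tot,
       " over ", length(reactants), " species")
}

#' Build a single mass-action reaction
#'
#' @param id Reaction identifier, unique within a network.
#' @param reactants,products Named integer vectors (species name -> count).
#'   Use `c()` / `NULL` for none.
#' @param rate Name of the rate parameter.
#' @param modifier Optional name of a parameter acting as a constant
#'   multiplicative concentration (a catalyst held at fixed level, e.g. an
#'   initiator caspase driving an activation step).
#' @return A `reaction` list with a derived `kind` field.
#' @export
reaction <- function(id, reactants = NULL, products = NULL, rate,
                     modifier = NULL) {
  reactants <- .as_stoich(reactants)
  products <- .as_stoich(products)
  structure(
    list(id = as.character(id), reactants = reactants, products = products,
         rate = as.character(rate),
         modifier = if (is.null(modifier) || is.na(modifier)) NA_character_
                    else as.character(modifier),
         kind = .reaction_kind(reactants)),
    class = "reaction")
}

.as_stoich <- function(x) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("stoichiometry must be a named vector (species name -> count)")
  }
  v <- as.integer(x)
  if (any(v <= 0L)) stop("stoichiometric counts must be positive integers")
  stats::setNames(v, names(x))
}

#' Assemble a validated mass-action reaction network
#'
#' The central container: an ordered species table, an ordered reaction list,
#' a parameter table, one designated input (control) parameter and one output
#' species. Both the deterministic vector field and the volume-scaled
#' stochastic propensities are derived from it.
#'
#' @param species A data frame with columns `name`, `initial_nM` and logical
#'   `output` (exactly one `TRUE`).
#' @param reactions A list of [reaction()] objects.
#' @param parameters Named numeric vector of positive rate constants (and any
#'   modifier levels, in nM).
#' @param input_parameter Name of the control parameter (must be in
#'   `parameters`).
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, parameters, input_parameter) {
  species <- tibble::as_tibble(species)
  stopifnot(all(c("name", "initial_nM", "output") %in% names(species)))
  species$name <- as.character(species$name)
  species$initial_nM <- as.numeric(species$initial_nM)
  species$output <- as.logical(species$output)
  if (anyDuplicated(species$name)) stop("species names must be unique")
  if (any(species$initial_nM < 0)) stop("initial concentrations must be >= 0")
  if (sum(species$output) != 1L) stop("exactly one species must be flagged as output")
  parameters <- unlist(parameters)
  if (is.null(names(parameters)) || any(!nzchar(names(parameters)))) {
    stop("parameters must be named")
  }
  if (any(parameters <= 0)) stop("parameters must be positive")
  if (!is.character(input_parameter) || length(input_parameter) != 1L ||
      !(input_parameter %in% names(parameters))) {
    stop("input_parameter must name an entry of `parameters`")
  }
  if (!length(reactions)) stop("a network needs at least one reaction")
  reactions <- lapply(reactions, function(r) {
    if (!inherits(r, "reaction")) stop("`reactions` must be a list of reaction() objects")
    r
  })
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("reaction ids must be unique")
  for (r in reactions) {
    unknown <- setdiff(c(names(r$reactants), names(r$products)), species$name)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references undeclared species: ",
           paste(unknown, collapse = ", "))
    }
    if (!(r$rate %in% names(parameters))) {
      stop("reaction '", r$id, "' references undeclared parameter '", r$rate, "'")
    }
    if (!is.na(r$modifier) && !(r$modifier %in% names(parameters))) {
      stop("reaction '", r$id, "' references undeclared modifier parameter '",
           r$modifier, "'")
    }
  }
  net <- structure(
    list(species = species, reactions = reactions,
         parameters = parameters, input_parameter = input_parameter,
         output_species = species$name[species$output]),
    class = "reaction_network")
  net$tables <- .network_tables(net)
  net
}

# Precompute structural tables: stoichiometry matrix (species x reactions),
# rate-law kind codes and reactant species indices.
.network_tables <- function(net) {
  sp <- net$species$name
  n <- length(sp)
  J <- length(net$reactions)
  stoich <- matrix(0L, n, J, dimnames = list(sp, NULL))
  kind <- integer(J)
  idx1 <- integer(J)
  idx2 <- integer(J)
  rate_name <- character(J)
  mod_name <- character(J)
  for (j in seq_len(J)) {
    r <- net$reactions[[j]]
    for (s in names(r$reactants)) stoich[s, j] <- stoich[s, j] - r$reactants[[s]]
    for (s in names(r$products)) stoich[s, j] <- stoich[s, j] + r$products[[s]]
    kind[j] <- match(r$kind, .KINDS)
    rs <- names(r$reactants)
    idx1[j] <- if (length(rs)) match(rs[1], sp) else 0L
    idx2[j] <- if (r$kind == "second_hetero") match(rs[2], sp) else 0L
    rate_name[j] <- r$rate
    mod_name[j] <- r$modifier
  }
  list(stoich = stoich, kind = kind, idx1 = idx1, idx2 = idx2,
       idx1s = pmax(idx1, 1L), idx2s = pmax(idx2, 1L),
       rate_name = rate_name, mod_name = mod_name,
       output_index = match(net$output_species, sp))
}

# Effective rate constant per reaction: k * modifier-level (if any).
.rates <- function(net) {
  tb <- net$tables
  k <- unname(net$parameters[tb$rate_name])
  has_mod <- !is.na(tb$mod_name)
  if (any(has_mod)) {
    k[has_mod] <- k[has_mod] * unname(net$parameters[tb$mod_name[has_mod]])
  }
  k
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf(
    "<reaction_network> %d species, %d reactions, %d parameters\n",
    nrow(x$species), length(x$reactions), length(x$parameters)))
  cat(sprintf("  input parameter: %s = %g\n  output species:  %s\n",
              x$input_parameter, x$parameters[[x$input_parameter]],
              x$output_species))
  invisible(x)
}

#' Replace parameter values (returns a new network)
#'
#' @param net A [reaction_network()].
#' @param ... Named scalar values, e.g. `set_parameters(net, k3 = 5)`.
#' @return The network with updated parameters.
#' @export
set_parameters <- function(net, ...) {
  upd <- c(...)
  unknown <- setdiff(names(upd), names(net$parameters))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  net$parameters[names(upd)] <- upd
  if (any(net$parameters <= 0)) stop("parameters must stay positive")
  net
}

#' Set the control (input) parameter value
#' @param net A [reaction_network()].
#' @param value Positive scalar (nM for concentration-like inputs).
#' @return Updated network.
#' @export
set_input <- function(net, value) {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  net$parameters[[net$input_parameter]] <- value
  net
}

#' Initial state of a network
#' @param net A [reaction_network()].
#' @param size Optional [system_size()]: if given, returns nearest-integer
#'   molecule counts; otherwise concentrations (nM).
#' @return Named numeric vector.
#' @export
initial_state <- function(net, size = NULL) {
  x <- stats::setNames(net$species$initial_nM, net$species$name)
  if (is.null(size)) return(x)
  round(convert_units(x, size, "to_counts"))
}

# ---- JSON (de)serialisation -------------------------------------------------

#' Read a reaction-network model file
#'
#' The JSON schema has top-level keys `species` (list of
#' `{name, initial_nM, output}`), `reactions` (list of
#' `{id, reactants, products, rate, modifier}`), `parameters` and
#' `input_parameter`. [save_model()] writes keys in that order and the pair
#' round-trips byte-identically.
#'
#' @param path Path to a model JSON file.
#' @return A validated [reaction_network()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse '", path, "': ",
                                           conditionMessage(e)))
  for (key in c("species", "reactions", "parameters", "input_parameter")) {
    if (is.null(doc[[key]])) stop("model file is missing required key '", key, "'")
  }
  species <- purrr::map_dfr(doc$species, function(s) {
    for (f in c("name", "initial_nM", "output")) {
      if (is.null(s[[f]])) stop("species entry is missing field '", f, "'")
    }
    tibble::tibble(name = s$name, initial_nM = s$initial_nM, output = s$output)
  })
  reactions <- purrr::map(doc$reactions, function(r) {
    for (f in c("id", "rate")) {
      if (is.null(r[[f]])) stop("reaction entry is missing field '", f, "'")
    }
    reaction(id = r$id,
             reactants = unlist(r$reactants),
             products = unlist(r$products),
             rate = r$rate,
             modifier = if (is.null(r$modifier)) NULL else r$modifier)
  })
  reaction_network(species, reactions, unlist(doc$parameters),
                   doc$input_parameter)
}

#' Write a reaction-network model file
#' @param net A [reaction_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname load_model
#' @export
save_model <- function(net, path) {
  doc <- list(
    species = purrr::pmap(net$species, function(name, initial_nM, output) {
      list(name = name, initial_nM = initial_nM, output = output)
    }),
    reactions = purrr::map(net$reactions, function(r) {
      list(id = r$id,
           reactants = as.list(r$reactants),
           products = as.list(r$products),
           rate = r$rate,
           modifier = if (is.na(r$modifier)) NULL else r$modifier)
    }),
    parameters = as.list(net$parameters),
    input_parameter = net$input_parameter)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}
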