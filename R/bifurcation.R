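# Branch tracing against the control parameter and saddle-node location.

#' Bifurcation diagram by natural-parameter continuation
#'
#' Sweeps the input parameter over `input_range`, re-solving for fixed points
#' at each value with warm starts from the previous step (solution reuse)
#' plus a fresh multi-start, and assembles the points into branches by
#' nearest-state matching. A state jump larger than `branch_tol` (relative)
#' starts a new branch with a warning.
#'
#' @param net A [reaction_network()].
#' @param input_range Length-2 positive numeric: control-parameter interval.
#' @param n_points Number of continuation steps.
#' @param seed Seed for the multi-start root searches.
#' @param branch_tol Relative state-discontinuity tolerance for branch
#'   matching.
#' @return An object of class `bifurcation_diagram`: list with `points` (a
#'   tibble `input_value`, `output_level`, `stability`, `branch`),
#'   `sn_location` (fold value of the input parameter, `NA` if no fold is
#'   bracketed) and `input_range`.
#' @export
bifurcation_diagram <- function(net, input_range, n_points = 60L, seed = 1L,
                                branch_tol = 0.25) {
  stopifnot(length(input_range) == 2L, all(input_range > 0),
            all(is.finite(input_range)), n_points >= 2L)
  grid <- seq(input_range[1], input_range[2], length.out = n_points)
  prev_states <- list()
  branches <- list()   # each: list(last_state, rows)
  rows <- vector("list", n_points)
  counts <- integer(n_points)
  for (i in seq_along(grid)) {
    neti <- set_input(net, grid[i])
    fps <- find_fixed_points(neti, seed = seed)
    # warm-start refinement from the previous step's solutions
    for (ps in prev_states) {
      r <- .newton(neti, ps)
      if (!is.null(r)) {
        dup <- any(vapply(fps$state, function(q)
          max(abs(r - q)) <= 1e-5 * max(1, max(abs(q))), logical(1)))
        if (!dup && nrow(fps)) {
          ev <- Re(eigen(ode_jacobian(neti, r), only.values = TRUE)$values)
          npos <- sum(ev > 1e-8)
          fps <- dplyr::bind_rows(fps, tibble::tibble(
            input_value = grid[i], output = r[neti$tables$output_index],
            stability = if (npos == 0L) "stable" else if (npos == 1L) "saddle" else "unstable",
            leading_eigenvalue = max(ev),
            state = list(stats::setNames(r, neti$species$name))))
        }
      }
    }
    counts[i] <- nrow(fps)
    prev_states <- fps$state
    # assign branch ids by nearest previous branch endpoint
    br_id <- integer(nrow(fps))
    for (k in seq_len(nrow(fps))) {
      st <- fps$state[[k]]
      best <- NA_integer_; bestd <- Inf
      for (b in seq_along(branches)) {
        d <- max(abs(st - branches[[b]]$last_state)) /
          max(1, max(abs(branches[[b]]$last_state)))
        if (d < bestd) { bestd <- d; best <- b }
      }
      if (is.na(best) || bestd > branch_tol) {
        branches[[length(branches) + 1L]] <- list(last_state = st)
        br_id[k] <- length(branches)
        if (!is.na(best) && i > 1L) {
          warning("branch jump detected at input value ", signif(grid[i], 6),
                  "; starting a new branch")
        }
      } else {
        branches[[best]]$last_state <- st
        br_id[k] <- best
      }
    }
    if (nrow(fps)) {
      rows[[i]] <- tibble::tibble(input_value = grid[i],
                                  output_level = fps$output,
                                  stability = fps$stability,
                                  branch = br_id)
    }
  }
  pts <- dplyr::bind_rows(rows)
  sn <- NA_real_
  flip <- which(diff(counts >= 3L) != 0L)
  if (length(flip)) {
    f <- flip[length(flip)]
    sn <- tryCatch(
      locate_saddle_node(net, c(grid[f], grid[f + 1]), seed = seed),
      error = function(e) NA_real_)
  }
  structure(list(points = pts, sn_location = sn, input_range = input_range,
                 output_species = net$output_species,
                 input_parameter = net$input_parameter),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("<bifurcation_diagram> %s over %s in [%g, %g]; SN at %s\n",
              x$output_species, x$input_parameter,
              x$input_range[1], x$input_range[2],
              ifelse(is.na(x$sn_location), "none bracketed",
                     signif(x$sn_location, 6))))
  invisible(x)
}

#' Locate a saddle-node fold of the control parameter
#'
#' Bisection on the number of coexisting fixed points (3 inside the bistable
#' window vs 1 outside), refined until the relative bracket width falls below
#' `tol`. Returns the fold location of the input parameter.
#'
#' @param net A [reaction_network()].
#' @param bracket Length-2 interval of input-parameter values whose fixed
#'   point counts differ (3 vs 1).
#' @param tol Relative bracket-width stopping tolerance.
#' @param seed Seed for the multi-start fixed-point searches.
#' @param n_starts Random starts per bisection step (warm starts from the
#'   previous step supplement them).
#' @return Fold location (same units as the input parameter, typically nM).
#' @export
locate_saddle_node <- function(net, bracket, tol = 1e-5, seed = 1L,
                               n_starts = 10L) {
  stopifnot(length(bracket) == 2L, all(bracket > 0), bracket[1] < bracket[2])
  count_at <- function(v, warm = NULL) {
    fps <- find_fixed_points(net, input_value = v, seed = seed,
                             n_starts = if (is.null(warm)) n_starts else 4L,
                             relax = is.null(warm))
    states <- fps$state
    if (!is.null(warm)) {
      neti <- set_input(net, v)
      for (w in warm) {
        r <- .newton(neti, w)
        if (!is.null(r)) {
          dup <- any(vapply(states, function(q)
            max(abs(r - q)) <= 1e-5 * max(1, max(abs(q))), logical(1)))
          if (!dup) states <- c(states, list(r))
        }
      }
    }
    list(n = length(states), states = states)
  }
  lo <- count_at(bracket[1]); hi <- count_at(bracket[2])
  multi_lo <- lo$n >= 3L; multi_hi <- hi$n >= 3L
  if (multi_lo == multi_hi) {
    stop("bracket does not straddle a fold: ", lo$n, " vs ", hi$n,
         " fixed points at the endpoints")
  }
  a <- bracket[1]; b <- bracket[2]
  warm <- c(lo$states, hi$states)
  while ((b - a) / max(abs(a), abs(b)) > tol) {
    m <- (a + b) / 2
    cm <- count_at(m, warm = warm)
    warm <- cm$states
    if ((cm$n >= 3L) == multi_lo) a <- m else b <- m
  }
  (a + b) / 2
}
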