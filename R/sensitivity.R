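# Parameter sensitivity spectra: local percent-perturbation analysis,
# variance-based (Sobol/Jansen) total effects, and Spearman rank comparison.

#' Local (percent-perturbation) sensitivity spectrum
#'
#' Perturbs every kinetic parameter (the designated input parameter is the
#' condition axis and is skipped) by `+/- delta` one at a time and records
#' the signed percentage response of the chosen output functional: the
#' saddle-node location, the mean first-passage time, or the quasi-potential
#' barrier height. The perturbation direction that increases the output
#' (right-shifts the fold / lengthens the switching time / raises the
#' barrier) is labelled the oncogenic direction and its magnitude is the
#' ranking statistic. MFPT evaluations reuse one master seed across all
#' perturbations (common random numbers).
#'
#' @param net A [reaction_network()].
#' @param output_kind One of `"sn_location"`, `"mfpt"`, `"barrier"`.
#' @param delta Perturbation fraction in (0, 0.2]; default 0.02.
#' @param condition Named list of evaluation conditions:
#'   `bracket` (for `sn_location`; defaults to the baseline fold +/- 20%),
#'   `input_value` (for `mfpt` / `barrier`), `size` (a [system_size()], for
#'   `mfpt`), `n_runs`, `t_max`, `threshold_fraction` (for `mfpt`),
#'   `n_points`, `log_space` (for `barrier`).
#' @param seed Master seed shared by all stochastic evaluations.
#' @param output_fn Optional custom output functional `function(net) ->
#'   scalar` replacing the built-in kinds (used mainly for validation).
#' @return An object of class `sensitivity_spectrum`: tibble `entries`
#'   (`parameter`, `pct_up`, `pct_down`, `oncogenic_direction`, `magnitude`,
#'   `rank`, `ok`), `baseline`, `output_kind`, `delta`, `condition`.
#' @export
local_spectrum <- function(net, output_kind = c("sn_location", "mfpt", "barrier"),
                           delta = 0.02, condition = list(), seed = 1L,
                           output_fn = NULL) {
  if (is.null(output_fn)) {
    output_kind <- match.arg(output_kind)
  } else {
    output_kind <- "custom"
  }
  stopifnot(delta > 0, delta <= 0.2)
  f <- output_fn %||% .output_functional(output_kind, condition, seed)
  baseline <- f(net)
  if (!is.finite(baseline)) stop("baseline output not computable at the given condition")
  if (is.null(output_fn) && output_kind == "sn_location" &&
      is.null(condition$bracket)) {
    condition$bracket <- baseline * c(0.8, 1.2)
    f <- .output_functional(output_kind, condition, seed)
  }
  pars <- setdiff(names(net$parameters), net$input_parameter)
  rows <- purrr::map_dfr(pars, function(pn) {
    vals <- purrr::map_dbl(c(up = 1 + delta, down = 1 - delta), function(fac) {
      net2 <- set_parameters(net, stats::setNames(net$parameters[[pn]] * fac, pn))
      tryCatch(f(net2), error = function(e) NA_real_)
    })
    pct <- 100 * (vals - baseline) / baseline
    ok <- all(is.finite(pct))
    if (!ok) {
      warning("parameter '", pn, "': output undefined after perturbation ",
              "(bistability lost?); excluded from ranking")
    }
    dir <- if (!ok) NA_character_ else if (pct[["up"]] >= pct[["down"]]) "up" else "down"
    tibble::tibble(parameter = pn,
                   pct_up = pct[["up"]], pct_down = pct[["down"]],
                   oncogenic_direction = dir,
                   magnitude = if (ok) abs(max(pct)) else NA_real_,
                   ok = ok)
  })
  rows$rank <- NA_integer_
  rows$rank[rows$ok] <- rank(-rows$magnitude[rows$ok], ties.method = "average")
  structure(list(entries = rows, baseline = baseline,
                 output_kind = output_kind, delta = delta,
                 condition = condition, seed = as.integer(seed)),
            class = "sensitivity_spectrum")
}

.output_functional <- function(output_kind, condition, seed) {
  switch(
    output_kind,
    sn_location = function(net) {
      br <- condition$bracket
      if (is.null(br)) {
        # coarse auto-bracket: scan the input axis for the fold
        iv <- net$parameters[[net$input_parameter]]
        br <- c(iv, iv * 4)
      }
      locate_saddle_node(net, br, seed = seed)
    },
    mfpt = function(net) {
      size <- condition$size %||% system_size(volume = 100)
      estimate_mfpt(net, size,
                    input_value = condition$input_value,
                    threshold_fraction = condition$threshold_fraction %||% 0.8,
                    n_runs = condition$n_runs %||% 200L,
                    t_max = condition$t_max, seed = seed)$mfpt
    },
    barrier = function(net) {
      barrier_height(net, input_value = condition$input_value,
                     n_points = condition$n_points %||% 60L,
                     log_space = condition$log_space %||% FALSE,
                     tol = condition$tol %||% 1e-6)$barrier
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sensitivity_spectrum <- function(x, ...) {
  cat(sprintf("<sensitivity_spectrum> %s, delta = %g%%, baseline = %.6g\n",
              x$output_kind, 100 * x$delta, x$baseline))
  print(dplyr::arrange(x$entries, .data$rank), n = 10)
  invisible(x)
}

#' Sobol total-effect and first-order indices of a black-box function
#'
#' Saltelli paired-matrix design on a Sobol quasi-random base sample, Jansen
#' estimators, and bootstrap confidence intervals. Rows for which the model
#' output is undefined (`NA`, e.g. a parameter draw that destroys
#' bistability) are rejected and the whole cross-row set is resampled from
#' the continuation of the sequence; the accepted and drawn counts are both
#' reported.
#'
#' @param f Function taking an `m x d` matrix of points in the unit cube (or
#'   in `ranges`, if given) and returning a numeric vector; `NA` marks an
#'   invalid draw.
#' @param d Input dimension.
#' @param n_base Base sample count (a power of two is recommended).
#' @param ranges Optional `d x 2` matrix of sampling intervals; points are
#'   mapped linearly from the unit cube.
#' @param seed Seed for the digital shift and the bootstrap.
#' @param n_boot Bootstrap replicates for the CIs.
#' @param max_reject Abort if the acceptance rate drops below 1% after this
#'   many attempts.
#' @return An object of class `sobol_spectrum`: tibble `entries` (`parameter`,
#'   `first_order`, `total_effect`, CI bounds), `n_base`, `n_accepted`,
#'   `n_drawn`, `variance`.
#' @export
sobol_indices <- function(f, d, n_base = 256L, ranges = NULL, seed = 1L,
                          n_boot = 200L, max_reject = 100L * n_base,
                          names = NULL) {
  stopifnot(d >= 1L, n_base >= 8L)
  if (!is.null(ranges)) {
    ranges <- matrix(as.numeric(ranges), ncol = 2L)
    stopifnot(nrow(ranges) == d)
  }
  map_pt <- function(U) {
    if (is.null(ranges)) return(U)
    sweep(sweep(U, 2L, ranges[, 2] - ranges[, 1], "*"), 2L, ranges[, 1], "+")
  }
  # stream of candidate cross-rows
  chunk <- 4L * n_base
  stream <- sobol_points(chunk, 2L * d, seed = seed)
  stream_pos <- 0L
  next_row <- function() {
    if (stream_pos >= nrow(stream)) {
      stream <<- rbind(stream,
                       sobol_points(chunk, 2L * d,
                                    seed = (as.integer(seed) + nrow(stream)) %%
                                      .Machine$integer.max,
                                    skip = 1L))
    }
    stream_pos <<- stream_pos + 1L
    stream[stream_pos, ]
  }
  fA <- numeric(n_base); fB <- numeric(n_base)
  fAB <- matrix(0, n_base, d)
  n_drawn <- 0L
  for (r in seq_len(n_base)) {
    repeat {
      u <- next_row()
      n_drawn <- n_drawn + 1L
      if (n_drawn > max_reject) {
        stop("Sobol sampling acceptance rate below 1%; check the ranges")
      }
      a <- u[seq_len(d)]; b <- u[d + seq_len(d)]
      pts <- matrix(rep(a, d + 2L), ncol = d, byrow = TRUE)
      pts[2L, ] <- b
      for (i in seq_len(d)) pts[2L + i, i] <- b[i]
      y <- f(map_pt(pts))
      if (all(is.finite(y))) {
        fA[r] <- y[1L]; fB[r] <- y[2L]; fAB[r, ] <- y[3L:(d + 2L)]
        break
      }
    }
  }
  est <- function(idx) {
    V <- stats::var(c(fA[idx], fB[idx]))
    st <- colMeans((fA[idx] - fAB[idx, , drop = FALSE])^2) / (2 * V)
    s1 <- 1 - colMeans((fB[idx] - fAB[idx, , drop = FALSE])^2) / (2 * V)
    list(st = st, s1 = s1, V = V)
  }
  point <- est(seq_len(n_base))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  boots_st <- matrix(0, n_boot, d)
  boots_s1 <- matrix(0, n_boot, d)
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n_base, replace = TRUE)
    e <- est(idx)
    boots_st[bb, ] <- e$st; boots_s1[bb, ] <- e$s1
  }
  if (is.null(names)) names <- paste0("x", seq_len(d))
  entries <- tibble::tibble(
    parameter = names,
    first_order = point$s1,
    total_effect = point$st,
    first_lo = apply(boots_s1, 2L, stats::quantile, 0.025),
    first_hi = apply(boots_s1, 2L, stats::quantile, 0.975),
    total_lo = apply(boots_st, 2L, stats::quantile, 0.025),
    total_hi = apply(boots_st, 2L, stats::quantile, 0.975))
  structure(list(entries = entries, n_base = n_base, n_accepted = n_base,
                 n_drawn = n_drawn, variance = point$V),
            class = "sobol_spectrum")
}

#' Sobol total-effect spectrum of the saddle-node location
#'
#' Draws kinetic parameter sets from per-parameter ranges (default:
#' log-uniform over half to twice the nominal value — an assumption, the
#' sampling space being a modelling choice) and estimates, with
#' [sobol_indices()], how much each parameter contributes to the variance of
#' the fold location. Draws that destroy bistability are rejected by the
#' cross-row resampling scheme, so the indices are conditional on the
#' bistable region.
#'
#' @param net A [reaction_network()].
#' @param ranges Optional named `d x 2` matrix (rows = non-input parameters)
#'   of multiplicative factors; default `[0.5, 2]` log-uniform per parameter.
#' @param n_base Base sample count.
#' @param seed Seed.
#' @param bracket_factor The fold is searched in
#'   `baseline SN * bracket_factor`; widen for aggressive ranges.
#' @param output_fn Optional replacement output: function(net) -> scalar or
#'   NA. Default: upper fold of the input parameter.
#' @return A `sobol_spectrum` (see [sobol_indices()]).
#' @export
sobol_total_effect <- function(net, ranges = NULL, n_base = 128L, seed = 1L,
                               bracket_factor = c(0.5, 1.5),
                               output_fn = NULL) {
  pars <- setdiff(names(net$parameters), net$input_parameter)
  d <- length(pars)
  nominal <- net$parameters[pars]
  if (is.null(ranges)) {
    lr <- cbind(log(0.5), log(2))
    ranges <- matrix(rep(lr, each = d), ncol = 2L)
  } else {
    ranges <- log(matrix(as.numeric(ranges), ncol = 2L))
  }
  base_sn <- NULL
  if (is.null(output_fn)) {
    base_sn <- tryCatch(
      .auto_sn(net, seed), error = function(e)
        stop("cannot locate the baseline fold: ", conditionMessage(e)))
    output_fn <- function(net2) {
      tryCatch(
        locate_saddle_node(net2, base_sn * bracket_factor, seed = seed),
        error = function(e) NA_real_)
    }
  }
  f <- function(U) {
    apply(U, 1L, function(u) {
      net2 <- set_parameters(net, stats::setNames(nominal * exp(u), pars))
      output_fn(net2)
    })
  }
  res <- sobol_indices(f, d, n_base = n_base, ranges = ranges, seed = seed,
                       names = pars)
  res$baseline_sn <- base_sn
  res
}

# Baseline upper fold: scan the input axis geometrically for the 3 -> 1
# fixed-point-count transition, then bisect.
.auto_sn <- function(net, seed = 1L) {
  iv <- net$parameters[[net$input_parameter]]
  grid <- iv * 2^seq(0, 4, by = 0.5)
  counts <- vapply(grid, function(v)
    nrow(find_fixed_points(net, input_value = v, seed = seed)), integer(1))
  flip <- which(diff(counts >= 3L) != 0L)
  if (!length(flip)) stop("no fold found above the nominal input value")
  locate_saddle_node(net, grid[c(flip[1], flip[1] + 1L)], seed = seed)
}

#' @export
print.sobol_spectrum <- function(x, ...) {
  cat(sprintf("<sobol_spectrum> n_base = %d (drawn %d), output variance %.4g\n",
              x$n_base, x$n_drawn, x$variance))
  print(dplyr::arrange(x$entries, dplyr::desc(.data$total_effect)), n = 10)
  invisible(x)
}

#' Spearman rank correlation between two sensitivity spectra
#'
#' Compares the per-parameter magnitudes of two spectra (or named numeric
#' vectors) with average ranks for ties, two-sided p-value.
#'
#' @param a,b `sensitivity_spectrum`, `sobol_spectrum`, or named numeric
#'   vectors over an identical parameter set (>= 3 entries).
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(a, b) {
  va <- .spectrum_values(a); vb <- .spectrum_values(b)
  miss_a <- setdiff(names(vb), names(va)); miss_b <- setdiff(names(va), names(vb))
  if (length(miss_a) || length(miss_b)) {
    stop("parameter sets differ: missing in first: [",
         paste(miss_a, collapse = ", "), "]; missing in second: [",
         paste(miss_b, collapse = ", "), "]")
  }
  keys <- names(va)
  if (length(keys) < 3L) stop("need at least 3 shared parameters")
  ct <- suppressWarnings(
    stats::cor.test(va[keys], vb[keys], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(keys))
}

.spectrum_values <- function(x) {
  if (inherits(x, "sensitivity_spectrum")) {
    e <- x$entries[x$entries$ok, ]
    return(stats::setNames(e$magnitude, e$parameter))
  }
  if (inherits(x, "sobol_spectrum")) {
    return(stats::setNames(x$entries$total_effect, x$entries$parameter))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("cannot extract a named sensitivity vector from an object of class ",
       paste(class(x), collapse = "/"))
}

#' Pairwise Spearman comparison of a set of spectra
#'
#' The pipeline's headline deliverable: the matrix of rank correlations
#' between sensitivity spectra obtained by different routes (fold location,
#' switching time, barrier height near and far from the fold, variance-based
#' indices).
#'
#' @param spectra Named list of spectra (see [spearman_rho()] for accepted
#'   types), all over the same parameter set.
#' @param out_csv Optional path: write the correlation table as CSV.
#' @return A tibble in long form (`a`, `b`, `rho`, `p_value`) with class
#'   `spectrum_comparison`; the wide matrix is in `attr(, "matrix")`.
#' @export
compare_spectra <- function(spectra, out_csv = NULL) {
  stopifnot(is.list(spectra), length(spectra) >= 2L,
            !is.null(names(spectra)), all(nzchar(names(spectra))))
  nm <- names(spectra)
  M <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  rows <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      r <- spearman_rho(spectra[[i]], spectra[[j]])
      M[i, j] <- r$rho
      if (i < j) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          a = nm[i], b = nm[j], rho = r$rho, p_value = r$p_value)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "matrix") <- M
  class(out) <- c("spectrum_comparison", class(out))
  if (!is.null(out_csv)) {
    utils::write.csv(cbind(spectrum = rownames(M), as.data.frame(M)),
                     out_csv, row.names = FALSE)
  }
  out
}
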