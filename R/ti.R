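#' A per-lambda series of Hamiltonian derivatives
#'
#' Container for the dH/dlambda samples recorded in one lambda window.
#'
#' @param values dH/dlambda samples, kJ/mol.
#' @param lam the window's coupling parameter in \[0, 1\].
#' @param dt sample spacing, ps.
#' @param burn_in leading span regarded as equilibration, ps; discarded by
#'   [window_mean()].
#' @return An object of class `derivative_series`.
#' @export
derivative_series <- function(values, lam, dt, burn_in = 0) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty derivative series")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  if (dt <= 0) stop("dt must be > 0")
  if (burn_in < 0) stop("burn_in must be >= 0")
  structure(list(values = values, lam = lam, dt = dt, burn_in = burn_in),
            class = "derivative_series")
}

#' @export
print.derivative_series <- function(x, ...) {
  cat(sprintf("derivative_series: lambda = %.4f, %d samples every %.3f ps (burn-in %.1f ps)\n",
              x$lam, length(x$values), x$dt, x$burn_in))
  invisible(x)
}

#' Window mean and block-averaged standard error
#'
#' Discards the first `burn_in` picoseconds of a derivative series (sample i
#' is taken at time `i * dt`) and returns the mean of the retained samples
#' together with a standard error from block averaging: the retained series
#' is split into `n_blocks` contiguous blocks and the SEM is the standard
#' deviation of the block means divided by `sqrt(n_blocks)`.  Block
#' averaging absorbs the autocorrelation of the underlying dynamics as long
#' as blocks are longer than the correlation time.
#'
#' @param series a [derivative_series()].
#' @param n_blocks number of blocks (default 10).
#' @return list with `mean` and `sem`, both kJ/mol.
#' @export
window_mean <- function(series, n_blocks = 10) {
  stopifnot(inherits(series, "derivative_series"))
  times <- seq_along(series$values) * series$dt
  keep <- series$values[times > series$burn_in]
  if (length(keep) == 0)
    stop("empty window: all samples fall inside the burn-in span")
  if (length(keep) < 2)
    stop("need more than one retained sample after burn-in removal")
  nb <- min(n_blocks, length(keep))
  idx <- cut(seq_along(keep), breaks = nb, labels = FALSE)
  bm <- vapply(split(keep, idx), mean, numeric(1))
  list(mean = mean(keep), sem = stats::sd(bm) / sqrt(length(bm)))
}

#' Uniform lambda schedule
#'
#' Equidistant coupling values including both endpoints.  Conventional
#' window counts are 41 (spacing 0.025) for relative transformations and
#' Lennard-Jones decoupling legs, and 11 (spacing 0.1) for Coulomb and
#' restraint legs.
#'
#' @param kind only `"uniform"` is defined.
#' @param n number of windows (>= 2).
#' @return numeric vector of lambdas from 0 to 1.
#' @export
lambda_schedule <- function(kind = "uniform", n = 41) {
  kind <- match.arg(kind, "uniform")
  if (n < 2) stop("a lambda schedule needs at least 2 windows")
  seq(0, 1, length.out = n)
}

#' Thermodynamic integration over a lambda schedule
#'
#' Estimates \deqn{\Delta G = \int_0^1 \langle \partial H / \partial \lambda
#' \rangle_\lambda \, d\lambda} by trapezoidal quadrature of the per-window
#' means.  Windows are sorted internally; duplicate lambdas are rejected.
#' The standard error combines the block-averaged window SEMs through the
#' trapezoid weights in quadrature, treating windows as independent
#' simulations.
#'
#' @param windows list of [derivative_series()] objects with distinct
#'   lambdas (>= 2).
#' @param n_blocks blocks per window for the SEM (see [window_mean()]).
#' @return An object of class `ti_result`: `delta_g`, `stderr`,
#'   `window_means`, `window_sems`, `schedule`, and `covers_endpoints`
#'   (FALSE triggers a warning; no extrapolation is performed).
#' @export
integrate_ti <- function(windows, n_blocks = 10) {
  if (length(windows) < 2) stop("need at least 2 lambda windows")
  stopifnot(all(vapply(windows, inherits, logical(1), "derivative_series")))
  lams <- vapply(windows, `[[`, numeric(1), "lam")
  if (anyDuplicated(lams))
    stop("duplicate lambda values in the schedule; ",
         "each window must be a distinct lambda")
  ord <- order(lams)
  lams <- lams[ord]
  windows <- windows[ord]
  wm <- lapply(windows, window_mean, n_blocks = n_blocks)
  means <- vapply(wm, `[[`, numeric(1), "mean")
  sems <- vapply(wm, `[[`, numeric(1), "sem")
  w <- trapezoid_weights(lams)
  covers <- isTRUE(all.equal(min(lams), 0)) && isTRUE(all.equal(max(lams), 1))
  if (!covers)
    warning("lambda schedule does not span [0, 1]; ",
            "integrating over the covered range only")
  structure(list(delta_g = sum(w * means),
                 stderr = sqrt(sum((w * sems)^2)),
                 window_means = means, window_sems = sems,
                 schedule = lams, covers_endpoints = covers),
            class = "ti_result")
}

trapezoid_weights <- function(lams) {
  n <- length(lams)
  w <- numeric(n)
  d <- diff(lams)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' @export
print.ti_result <- function(x, ...) {
  cat(sprintf("TI over %d windows: delta G = %.4f +- %.4f kJ/mol\n",
              length(x$schedule), x$delta_g, x$stderr))
  if (!x$covers_endpoints) cat("  (schedule does not span [0, 1])\n")
  invisible(x)
}

#' Run one thermodynamic-integration leg on the toy model
#'
#' Convenience driver: simulates every window of a lambda schedule under the
#' given alchemical Hamiltonian and integrates the result.  Per-window seeds
#' are derived from `params$seed` with [child_seed()] so windows are
#' independent and individually reproducible.
#'
#' @param alch an [alchemical_hamiltonian()] template (its `lam` is swept).
#' @param schedule lambda values, e.g. [lambda_schedule()].
#' @param params a [simulation_params()]; `burn_in_steps` applies per window.
#' @param name leg label attached to the returned [leg_result()].
#' @return list with `leg` (a [leg_result()]), `ti` (the [ti_result]) and
#'   `series` (the per-window derivative series).
#' @export
ti_leg <- function(alch, schedule, params, name = "leg") {
  series <- lapply(seq_along(schedule), function(i) {
    p <- params
    p$seed <- child_seed(params$seed, i)
    sample_dhdl(alch, schedule[i], p)
  })
  ti <- integrate_ti(series)
  list(leg = leg_result(name, ti$delta_g, ti$stderr), ti = ti, series = series)
}
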