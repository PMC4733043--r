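#' Simulation configuration
#'
#' Collects everything a stochastic run needs: the model rates, the initial
#' organelle count, the duration, the integration scheme and its step size,
#' the RNG seed and the divergence guard.
#'
#' Two schemes are provided. \code{"event_driven"} is the exact stochastic
#' simulation algorithm (Gillespie direct method): waiting times are
#' exponential in the summed propensity and one event fires per draw.
#' \code{"fixed_step"} advances time in steps of \code{dt} and fires at most
#' one event per step, chosen by comparing a single uniform draw against the
#' cumulative first-order event probabilities; it is accurate when the summed
#' per-step probability is small (the default \code{dt = 1e-4} keeps it
#' O(1e-3) for typical rates).
#'
#' @param rates A \code{\link{model_rates}} object.
#' @param n0 Initial organelle count (non-negative integer; default 0).
#' @param t_end Duration of the run in model time units.
#' @param dt Time step for the fixed-step scheme (default \code{1e-4};
#'   ignored by the event-driven scheme).
#' @param seed Integer RNG seed; identical configuration and seed reproduce
#'   the run exactly. Ensembles derive independent per-cell streams from
#'   this seed by a counter-based split.
#' @param scheme \code{"event_driven"} (default) or \code{"fixed_step"}.
#' @param divergence_cap Abort threshold on the organelle count (default
#'   \code{1e6}): runs in a divergent regime terminate informatively instead
#'   of looping forever.
#'
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(rates, n0 = 0L, t_end, dt = 1e-4, seed,
                              scheme = c("event_driven", "fixed_step"),
                              divergence_cap = 1e6) {
  rates <- as_model_rates(rates)
  scheme <- match.arg(scheme)
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 0 || n0 != floor(n0))
    stop("'n0' must be a single non-negative integer", call. = FALSE)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end < 0)
    stop("'t_end' must be a single non-negative number", call. = FALSE)
  if (scheme == "fixed_step" && (!is.numeric(dt) || dt <= 0))
    stop("'dt' must be positive for the fixed-step scheme", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed) || seed != floor(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer", call. = FALSE)
  structure(list(rates = rates, n0 = as.integer(n0), t_end = t_end, dt = dt,
                 seed = as.numeric(seed), scheme = scheme,
                 divergence_cap = divergence_cap),
            class = "simulation_config")
}

divergence_error <- function(config, where) {
  reg <- classify_regime(config$rates)
  verdict <- if (reg$has_limiting_distribution)
    sprintf("regime %s admits a limiting distribution; the cap may be too low for these rates", reg$reason)
  else
    sprintf("regime %s has no limiting distribution", reg$reason)
  stop(structure(class = c("orgdist_divergence_error", "error", "condition"),
                 list(message = sprintf(
                        "%s: organelle count exceeded the divergence cap %g (%s)",
                        where, config$divergence_cap, verdict),
                      call = NULL)))
}

#' Simulate a single-cell trajectory
#'
#' Runs one cell forward from \code{n0} for \code{t_end} time units under
#' the configured scheme. The returned trajectory records the initial state
#' and every event; between records the count is constant, and successive
#' counts differ by exactly one.
#'
#' @param config A \code{\link{simulation_config}}.
#'
#' @return An object of class \code{"trajectory"}: a list with \code{time},
#'   \code{count} (aligned vectors), \code{t_end} and \code{config}.
#' @examples
#' cfg <- simulation_config(model_rates(2, 0.9, 1, 0.02), n0 = 0,
#'                          t_end = 50, seed = 1)
#' traj <- simulate_trajectory(cfg)
#' trajectory_stats(traj)
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  r <- config$rates
  res <- .sim_trajectory_cpp(r$k_de_novo, r$k_fission, r$gamma, r$k_fusion,
                             config$n0, config$t_end, config$dt,
                             config$scheme == "fixed_step",
                             config$divergence_cap, config$seed)
  if (res$diverged) divergence_error(config, "simulate_trajectory")
  structure(list(time = res$time, count = res$count,
                 t_end = config$t_end, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Single-cell trajectory: %d events over %g time units (final n = %d)\n",
              length(x$time) - 1L, x$t_end, x$count[length(x$count)]))
  invisible(x)
}

#' Time-averaged moments of a trajectory
#'
#' Time-weighted mean, variance and Fano factor of the organelle count over
#' the post-burn-in portion of a trajectory. At equilibrium these converge
#' to the moments of the limiting distribution (the single-cell counterpart
#' of ensemble sampling).
#'
#' @param traj A \code{"trajectory"}.
#' @param burn_in Fraction of \code{t_end} discarded from the start before
#'   averaging (default 0.2), allowing the run to forget its initial state.
#'
#' @return A list with \code{mean}, \code{variance}, \code{fano} and
#'   \code{fano_defined}.
#' @export
trajectory_stats <- function(traj, burn_in = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in >= 1)
    stop("'burn_in' must be in [0, 1)", call. = FALSE)
  t0 <- burn_in * traj$t_end
  times <- c(traj$time, traj$t_end)
  # piecewise-constant count; clip segments to [t0, t_end]
  seg_start <- pmax(times[-length(times)], t0)
  seg_end <- pmax(times[-1], t0)
  w <- seg_end - seg_start
  keep <- w > 0
  w <- w[keep]
  n <- traj$count[keep]
  W <- sum(w)
  m <- sum(w * n) / W
  v <- sum(w * n^2) / W - m^2
  v <- max(v, 0)
  if (m > 0) list(mean = m, variance = v, fano = v / m, fano_defined = TRUE)
  else list(mean = m, variance = v, fano = NaN, fano_defined = FALSE)
}

#' Simulate an ensemble of cells observed at one time
#'
#' Runs \code{n_cells} independent trajectories from a shared configuration
#' (per-cell RNG streams derived from the master seed by a counter split)
#' and records each cell's organelle count at the observation time
#' \code{tau}, as when imaging a field of cells at one moment. As
#' \code{tau} grows the histogram converges to the limiting distribution.
#'
#' @param config A \code{\link{simulation_config}} (its \code{t_end} is
#'   ignored in favour of \code{tau}).
#' @param n_cells Number of cells (at least 1).
#' @param tau Observation time.
#'
#' @return An object of class \code{"ensemble_snapshot"}: a list with
#'   \code{tau}, \code{n} (counts observed), \code{cells} (cells per count,
#'   summing to \code{n_cells}), \code{n_cells} and \code{config}.
#' @examples
#' cfg <- simulation_config(model_rates(2, 0.9, 1, 0.02), n0 = 1,
#'                          t_end = 15, seed = 1)
#' snap <- simulate_ensemble(cfg, n_cells = 1000, tau = 15)
#' @export
simulate_ensemble <- function(config, n_cells, tau = config$t_end) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != floor(n_cells))
    stop("'n_cells' must be a positive integer", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("'tau' must be a single non-negative time", call. = FALSE)
  r <- config$rates
  res <- .sim_ensemble_cpp(r$k_de_novo, r$k_fission, r$gamma, r$k_fusion,
                           config$n0, tau, config$dt,
                           config$scheme == "fixed_step",
                           config$divergence_cap, config$seed,
                           as.integer(n_cells))
  if (res$diverged) divergence_error(config, "simulate_ensemble")
  tab <- table(res$counts)
  structure(list(tau = tau,
                 n = as.integer(names(tab)),
                 cells = as.integer(tab),
                 counts = as.integer(res$counts),
                 n_cells = as.integer(n_cells),
                 config = config),
            class = "ensemble_snapshot")
}

#' @export
print.ensemble_snapshot <- function(x, ...) {
  cat(sprintf("Ensemble snapshot: %d cells at tau = %g; counts span %d..%d\n",
              x$n_cells, x$tau, min(x$n), max(x$n)))
  invisible(x)
}

#' Total-variation distance between a snapshot and a count distribution
#'
#' Half the L1 distance between the ensemble's empirical frequencies and a
#' reference distribution (typically the solver's limiting distribution);
#' useful for tracking convergence to equilibrium as the observation time
#' grows.
#'
#' @param snapshot An \code{"ensemble_snapshot"}.
#' @param dist A \code{"count_distribution"}.
#' @return The total-variation distance in \code{[0, 1]}.
#' @export
snapshot_tv_distance <- function(snapshot, dist) {
  stopifnot(inherits(snapshot, "ensemble_snapshot"),
            inherits(dist, "count_distribution"))
  all_n <- sort(unique(c(snapshot$n, dist$n)))
  emp <- numeric(length(all_n))
  emp[match(snapshot$n, all_n)] <- snapshot$cells / snapshot$n_cells
  ref <- numeric(length(all_n))
  ref[match(dist$n, all_n)] <- dist$probabilities
  0.5 * (sum(abs(emp - ref)) + dist$tail_bound)
}
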