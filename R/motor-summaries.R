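#' Single-filament motility statistics of a trajectory ensemble
#'
#' Velocity is the ensemble total anchor displacement divided by the total
#' simulated time (unbound intervals included).  A run is a maximal interval
#' with at least one head bound; run length is the anchor displacement over
#' the run, and a run still open at `t_max` contributes the distance
#' travelled so far.  A trajectory in which no head ever binds contributes
#' zero displacement and no runs.
#'
#' @param trajectories list of `motor_trajectory` objects simulated with
#'   `n_filaments = 1` and identical parameters.
#' @param cluster the [cluster_config()] used (consistency check).
#' @return object of class `single_filament_stats` with fields `velocity`
#'   (um/s), `run_length` (um), `n_runs`, standard errors, and `no_binding`
#'   flag when the ensemble contains no run at all (run length reported 0).
#' @export
single_filament_summary <- function(trajectories, cluster) {
  .check_ensemble(trajectories, cluster, n_filaments = 1L)
  t_tot <- sum(vapply(trajectories, function(x) x$t_final, 0))
  disp <- vapply(trajectories, function(x) x$displacement[1], 0)
  v_i <- disp / vapply(trajectories, function(x) x$t_final, 0)
  runs <- unlist(lapply(trajectories, function(x) x$run_lengths))
  no_binding <- length(runs) == 0L
  structure(list(
    velocity = sum(disp) / t_tot,
    run_length = if (no_binding) 0 else mean(runs),
    n_runs = length(runs),
    se_velocity = if (length(v_i) > 1) sd(v_i) / sqrt(length(v_i)) else NA_real_,
    se_run_length = if (length(runs) > 1) sd(runs) / sqrt(length(runs)) else NA_real_,
    no_binding = no_binding,
    total_time = t_tot,
    n_trajectories = length(trajectories)
  ), class = "single_filament_stats")
}

#' @export
print.single_filament_stats <- function(x, ...) {
  cat(sprintf("single-filament stats: v = %.4g um/s, run length = %.4g um (%d runs)\n",
              x$velocity, x$run_length, x$n_runs))
  invisible(x)
}

#' Two-filament strain rate and crosslink probability
#'
#' `p_cl` is the time-weighted fraction of the simulation during which both
#' filaments carry at least one bound head.  `epsilon` is the relative
#' sliding strain rate: anchor displacements of the two (antiparallel)
#' filaments accrued while crosslinked, summed and divided by the total
#' simulated time.  A single-headed cluster can never bridge two filaments,
#' so `p_cl = 0` and `epsilon = 0` exactly.
#'
#' @inheritParams single_filament_summary
#' @return object of class `two_filament_stats` with `epsilon` (um/s),
#'   `p_cl`, and standard errors over trajectories.
#' @export
two_filament_summary <- function(trajectories, cluster) {
  .check_ensemble(trajectories, cluster, n_filaments = 2L)
  t_i <- vapply(trajectories, function(x) x$t_final, 0)
  p_i <- vapply(trajectories, function(x) x$time_crosslinked, 0) / t_i
  e_i <- vapply(trajectories, function(x) x$strain, 0) / t_i
  n <- length(trajectories)
  structure(list(
    epsilon = sum(vapply(trajectories, function(x) x$strain, 0)) / sum(t_i),
    p_cl = sum(vapply(trajectories, function(x) x$time_crosslinked, 0)) / sum(t_i),
    se_epsilon = if (n > 1) sd(e_i) / sqrt(n) else NA_real_,
    se_p_cl = if (n > 1) sd(p_i) / sqrt(n) else NA_real_,
    total_time = sum(t_i),
    n_trajectories = n
  ), class = "two_filament_stats")
}

#' @export
print.two_filament_stats <- function(x, ...) {
  cat(sprintf("two-filament stats: epsilon = %.4g um/s, P_cl = %.4g\n",
              x$epsilon, x$p_cl))
  invisible(x)
}

.check_ensemble <- function(trajectories, cluster, n_filaments) {
  if (length(trajectories) == 0L) stop("empty trajectory ensemble")
  ok <- vapply(trajectories, function(x)
    inherits(x, "motor_trajectory") && x$cluster$n_filaments == n_filaments, TRUE)
  if (!all(ok))
    stop(sprintf("all trajectories must be motor_trajectory objects with n_filaments = %d",
                 n_filaments))
  if (!missing(cluster) && !is.null(cluster)) {
    same <- vapply(trajectories, function(x) x$cluster$n_heads == cluster$n_heads, TRUE)
    if (!all(same)) stop("trajectories were simulated with a different cluster")
  }
  invisible(TRUE)
}

#' Stationary probability that a head is bound
#'
#' For the irreversible three-state cycle the long-run fraction of time a
#' head spends bound (states 2 and 3) follows from renewal theory as the
#' bound mean holding time over the mean cycle time:
#' `p = (1/k23 + 1/k31) / (1/k12 + 1/k23 + 1/k31)` with
#' `k31 = k31_per_atp * atp`.  At `atp = 0` the bound states are absorbing
#' and `p = 1`.
#'
#' @inheritParams gillespie_trajectory
#' @return bound probability in `[0, 1]`.
#' @examples
#' stationary_bound_fraction(rate_constants(1, 1, 1), atp = 1)  # 2/3
#' @export
stationary_bound_fraction <- function(rates, atp) {
  stopifnot(inherits(rates, "rate_constants"))
  if (any(atp < 0)) stop("atp must be non-negative")
  k31 <- k31_effective(rates, atp)
  ifelse(k31 == 0, 1,
         (1 / rates$k23 + 1 / k31) /
           (1 / rates$k12 + 1 / rates$k23 + 1 / k31))
}

#' Closed-form crosslink probability for independent heads
#'
#' With heads bound independently with probability `p` and each binding
#' choosing one of two filaments with equal probability, inclusion-exclusion
#' over the two filaments gives the probability that both are occupied:
#' `1 - 2 (1 - p/2)^n + (1 - p)^n`.  This is the exact stationary limit the
#' Gillespie simulation must reproduce, and serves as its oracle.
#'
#' @param p_bound per-head bound probability in `[0, 1]` (vectorized).
#' @param n_heads cluster valency, >= 1.
#' @return crosslink probability in `[0, 1]`.
#' @examples
#' crosslink_probability_closed_form(0.5, 4)  # 0.4297
#' @export
crosslink_probability_closed_form <- function(p_bound, n_heads) {
  if (any(p_bound < 0 | p_bound > 1)) stop("p_bound must lie in [0, 1]")
  if (any(n_heads < 1)) stop("n_heads must be >= 1")
  1 - 2 * (1 - p_bound / 2)^n_heads + (1 - p_bound)^n_heads
}
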