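#' Simulate one motor-cluster trajectory by the Gillespie algorithm
#'
#' Evolves every head of a cluster through its three-state catalytic cycle
#' by exact stochastic simulation over all allowed transitions.  When a head
#' binds (1 to 2) it lands on a filament chosen uniformly at random (two
#' filaments) at a position drawn from Normal(x + s/2, sd = s/2), where x is
#' that filament's anchor; the anchor is re-evaluated after every transition
#' as the rearmost bound head plus s/2.  At `atp = 0` the unbinding rate is
#' zero and heads that reach rigor stay there.
#'
#' @param cluster a [cluster_config()].
#' @param rates a [rate_constants()].
#' @param atp ATP concentration, uM (>= 0).
#' @param t_max simulated time, s (>= 0).
#' @param seed integer seed; identical seeds and parameters give
#'   bit-identical trajectories.
#' @param record_events keep the full event log (set `FALSE` for large
#'   ensembles where only the summary statistics are needed).
#' @param strain_establish convention for the event that establishes a
#'   crosslink: if `TRUE` (default) strain accrues at every event at which
#'   the cluster is crosslinked immediately before or immediately after
#'   the transition, so the anchor jump of the crosslink-establishing
#'   binding counts as sliding; if `FALSE` only events with both filaments
#'   bound immediately before contribute.  The default reproduces the
#'   monotone increase of the strain rate with ATP expected of the model.
#' @return an object of class `motor_trajectory`: the event log (`t`, `head`,
#'   `transition` coded 12/23/31, `filament`, `position`), accumulated
#'   per-filament anchor displacement, sliding strain, crosslinked and bound
#'   times, run lengths, and the final head states.
#' @examples
#' tr <- gillespie_trajectory(cluster_config(4), rate_constants(10, 10, 0.1),
#'                            atp = 100, t_max = 10, seed = 1)
#' head(tr$events)
#' @export
gillespie_trajectory <- function(cluster, rates, atp, t_max, seed,
                                 record_events = TRUE,
                                 strain_establish = TRUE) {
  stopifnot(inherits(cluster, "cluster_config"), inherits(rates, "rate_constants"))
  if (!is.finite(atp) || atp < 0) stop("atp must be non-negative")
  if (!is.finite(t_max) || t_max < 0) stop("t_max must be non-negative")
  set.seed(as.integer(seed))
  res <- gillespie_core(cluster$n_heads, cluster$n_filaments, cluster$step_size,
                        rates$k12, rates$k23, k31_effective(rates, atp),
                        t_max, record_events, strain_establish)
  res$seed <- as.integer(seed)
  res$cluster <- cluster
  res$rates <- rates
  res$atp <- atp
  class(res) <- "motor_trajectory"
  res
}

#' @export
print.motor_trajectory <- function(x, ...) {
  n_ev <- if (is.null(x$events)) NA_integer_ else nrow(x$events)
  cat(sprintf(
    "motor trajectory: %d heads on %d filament(s), t = %g s, %s events\n",
    x$cluster$n_heads, x$cluster$n_filaments, x$t_final,
    ifelse(is.na(n_ev), "unrecorded", format(n_ev))))
  invisible(x)
}

#' Simulate an ensemble of independent trajectories
#'
#' Replicate seeds are derived from `seed` with [derive_seeds()].
#'
#' @inheritParams gillespie_trajectory
#' @param reps number of independent trajectories.
#' @return list of `motor_trajectory` objects.
#' @export
simulate_ensemble <- function(cluster, rates, atp, t_max, reps, seed,
                              record_events = FALSE) {
  stopifnot(reps >= 1)
  seeds <- derive_seeds(seed, reps)
  lapply(seeds, function(s)
    gillespie_trajectory(cluster, rates, atp, t_max, s, record_events))
}
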