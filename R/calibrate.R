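#' Calibration targets: printed single-filament endpoints for the tetramer
#'
#' Measured tetramer motility used to pin down the rate constants:
#' 0.5 um/s with 4 um run length at 10 uM ATP, and 10 um/s with 0.5 um run
#' length at 500 uM ATP.
#'
#' @return data.frame with columns `atp`, `velocity`, `run_length`.
#' @export
calibration_targets <- function() {
  data.frame(atp = c(10, 500), velocity = c(0.5, 10), run_length = c(4, 0.5))
}

#' Default logarithmic scan grid for the rate constants
#'
#' 12 log-spaced points per rate over `[0.1, 1e3]` 1/s for `k12` and `k23`
#' and `[1e-3, 10]` 1/(s uM) for `k31_per_atp`.
#'
#' @param n points per rate.
#' @return list of three numeric vectors.
#' @export
default_scan_grid <- function(n = 12) {
  list(k12 = 10^seq(-1, 3, length.out = n),
       k23 = 10^seq(-1, 3, length.out = n),
       k31_per_atp = 10^seq(-3, 1, length.out = n))
}

#' Scan rate constants against single-filament motility targets
#'
#' Simulates the cluster on a single filament at every grid point and every
#' target ATP concentration and returns the grid point minimizing the summed
#' squared log-error of simulated versus target velocity and run length.
#'
#' @param targets data.frame with columns `atp`, `velocity`, `run_length`
#'   (see [calibration_targets()]).
#' @param scan_grid list with numeric vectors `k12`, `k23`, `k31_per_atp`;
#'   the full outer grid is scanned (see [default_scan_grid()]).
#' @param sim_params list: `cluster` (a [cluster_config()], default tetramer),
#'   `t_max` (s per trajectory), `reps`, `seed`.
#' @param tol relative error above which the result is flagged
#'   `within_tol = FALSE` (a warning, not an error; the best point is still
#'   returned).
#' @return list of class `rate_calibration`: `rates` (the best
#'   [rate_constants()]), `loss`, `achieved` (per-target simulated velocity
#'   and run length with relative errors), `within_tol`, and the scanned
#'   grid sizes.
#' @export
calibrate_rates <- function(targets, scan_grid, sim_params = list(), tol = 0.2) {
  if (is.null(targets) || nrow(targets) == 0) stop("targets must be non-empty")
  stopifnot(all(c("atp", "velocity", "run_length") %in% names(targets)))
  if (any(lengths(scan_grid) == 0)) stop("scan_grid must be non-empty")
  stopifnot(all(c("k12", "k23", "k31_per_atp") %in% names(scan_grid)))
  p <- utils::modifyList(
    list(cluster = cluster_config(4), t_max = 30, reps = 3, seed = 1),
    sim_params)

  grid <- expand.grid(k12 = scan_grid$k12, k23 = scan_grid$k23,
                      k31_per_atp = scan_grid$k31_per_atp,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(p$seed, nrow(grid))

  eval_point <- function(rates, seed) {
    loss <- 0
    for (j in seq_len(nrow(targets))) {
      st <- .sim_single_filament(p$cluster, rates, targets$atp[j], p$t_max,
                                 p$reps, seed + j)
      if (!is.finite(st$velocity) || st$velocity <= 0 || st$no_binding ||
          st$run_length <= 0) return(Inf)
      loss <- loss + log(st$velocity / targets$velocity[j])^2 +
        log(st$run_length / targets$run_length[j])^2
    }
    loss
  }

  losses <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- rate_constants(grid$k12[i], grid$k23[i], grid$k31_per_atp[i])
    losses[i] <- eval_point(r, seeds[i])
  }
  best <- which.min(losses)
  rates <- rate_constants(grid$k12[best], grid$k23[best], grid$k31_per_atp[best])

  # re-simulate the winner with more statistics for the achieved table
  achieved <- do.call(rbind, lapply(seq_len(nrow(targets)), function(j) {
    st <- .sim_single_filament(p$cluster, rates, targets$atp[j],
                               max(p$t_max, 60), max(p$reps, 10),
                               seeds[best] + 1000L + j)
    data.frame(atp = targets$atp[j],
               velocity = st$velocity, run_length = st$run_length,
               target_velocity = targets$velocity[j],
               target_run_length = targets$run_length[j],
               rel_err_velocity = abs(st$velocity / targets$velocity[j] - 1),
               rel_err_run_length = abs(st$run_length / targets$run_length[j] - 1))
  }))
  within_tol <- all(achieved$rel_err_velocity <= tol,
                    achieved$rel_err_run_length <= tol)
  if (!within_tol)
    warning("no scanned grid point reproduces all targets within tolerance; best point returned")
  structure(list(rates = rates, loss = losses[best], achieved = achieved,
                 within_tol = within_tol, grid_size = lengths(scan_grid),
                 seed = p$seed),
            class = "rate_calibration")
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat("rate calibration", if (x$within_tol) "(within tolerance)" else "(OUTSIDE tolerance)", "\n")
  print(x$rates)
  print(x$achieved, digits = 3)
  invisible(x)
}

.sim_single_filament <- function(cluster, rates, atp, t_max, reps, seed) {
  trajs <- simulate_ensemble(cluster, rates, atp, t_max, reps, seed)
  single_filament_summary(trajs, cluster)
}

#' Two-stage calibration of the tetramer rate constants
#'
#' Convenience driver: a coarse scan over [default_scan_grid()] followed by
#' a local log-spaced refinement (one coarse grid step around the best
#' coarse point) with longer simulations.  Returns the refined
#' `rate_calibration`.
#'
#' @param seed master seed.
#' @param coarse_n,refine_n points per rate in the two stages.
#' @param sim_params overrides passed to [calibrate_rates()] (same defaults).
#' @export
calibrate_motor_rates <- function(seed = 1, coarse_n = 12, refine_n = 7,
                                  sim_params = list()) {
  coarse <- calibrate_rates(calibration_targets(), default_scan_grid(coarse_n),
                            utils::modifyList(list(seed = seed), sim_params),
                            tol = Inf)
  step <- 10^(4 / (coarse_n - 1))  # ratio between adjacent coarse points
  local_grid <- function(center, lo, hi) {
    g <- 10^seq(log10(center / step), log10(center * step), length.out = refine_n)
    g[g >= lo & g <= hi]
  }
  grid2 <- list(
    k12 = local_grid(coarse$rates$k12, 1e-2, 1e4),
    k23 = local_grid(coarse$rates$k23, 1e-2, 1e4),
    k31_per_atp = local_grid(coarse$rates$k31_per_atp, 1e-4, 1e2))
  refined <- calibrate_rates(
    calibration_targets(), grid2,
    utils::modifyList(list(seed = seed + 1L, t_max = 60, reps = 6), sim_params))
  refined$coarse <- coarse
  refined
}
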