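#' Rate constants of the three-state motor-head cycle
#'
#' Each enzymatic head cycles through three states: (1) unbound with ATP,
#' (2) bound post-powerstroke with ADP, (3) bound and nucleotide free
#' (rigor).  Transitions are irreversible.  Hydrolysis and binding (1 to 2)
#' occur at `k12`; ADP release (2 to 3) at `k23`; ATP uptake and unbinding
#' (3 to 1) at `k31_per_atp * [ATP]`, linear in ATP concentration, so that
#' at vanishing ATP heads accumulate in rigor.
#'
#' @param k12 rate 1/s, state 1 to 2 (hydrolysis + binding).
#' @param k23 rate 1/s, state 2 to 3 (ADP release).
#' @param k31_per_atp rate coefficient 1/(s uM); effective unbinding rate is
#'   `k31_per_atp * atp`.
#' @return an object of class `rate_constants`.
#' @examples
#' rate_constants(100, 100, 1)
#' @export
rate_constants <- function(k12, k23, k31_per_atp) {
  vals <- c(k12 = k12, k23 = k23, k31_per_atp = k31_per_atp)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rate constants must be finite and strictly positive")
  structure(as.list(vals), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("motor-head cycle rates: k12 = %g /s, k23 = %g /s, k31 = %g /(s uM) * [ATP]\n",
              x$k12, x$k23, x$k31_per_atp))
  invisible(x)
}

#' Effective unbinding rate at a given ATP concentration
#' @param rates a [rate_constants()] object.
#' @param atp ATP concentration, uM (>= 0).
#' @return `k31_per_atp * atp`, 1/s.
#' @export
k31_effective <- function(rates, atp) {
  stopifnot(inherits(rates, "rate_constants"))
  if (any(atp < 0)) stop("atp must be non-negative")
  rates$k31_per_atp * atp
}

#' Motor-cluster configuration
#'
#' A synthetic motor cluster couples `n_heads` independent enzymatic heads
#' through a common multimerization domain.  The cluster walks on one
#' filament (motility statistics) or bridges two (strain and crosslinking
#' statistics).
#'
#' @param n_heads cluster valency n, 1..16 (experiments use 3, 4, 8).
#' @param step_size average step length s, um.  The default 0.036 um is the
#'   actin pseudo-helical repeat; the rate calibration absorbs this choice.
#' @param n_filaments 1 or 2.
#' @param c_m dimensionless motor concentration (enters the elasticity
#'   model, not the kinetics); 1 by convention.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(n_heads, step_size = 0.036, n_filaments = 1, c_m = 1) {
  if (!(n_heads %in% 1:16)) stop("n_heads must be an integer in 1..16")
  if (!is.finite(step_size) || step_size <= 0) stop("step_size must be > 0")
  if (!(n_filaments %in% 1:2)) stop("n_filaments must be 1 or 2")
  structure(list(n_heads = as.integer(n_heads), step_size = step_size,
                 n_filaments = as.integer(n_filaments), c_m = c_m),
            class = "cluster_config")
}

#' @export
print.cluster_config <- function(x, ...) {
  cat(sprintf("motor cluster: %d heads, step %g um, %d filament(s)\n",
              x$n_heads, x$step_size, x$n_filaments))
  invisible(x)
}
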