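#' Hydrodynamic scaling parameters
#'
#' Parameters of the map from microscopic curves to nematic-scale
#' predictions.  Activity follows `alpha = alpha0 * epsilon^beta` and the
#' elastic constant is augmented linearly by crosslinkers,
#' `K = k0 + kappa * c_e` with effective crosslinker concentration
#' `c_e = c_m * P_cl + c_p`.  The working defaults are `kappa = 10 * k0`
#' and `beta = 0.1`; all proportionality constants are 1 so predicted
#' curves are reported normalized.
#'
#' @param k0 baseline elastic constant from excluded volume (model units).
#' @param kappa crosslink elasticity coefficient (energetic penalty per unit
#'   crosslinker concentration).
#' @param beta activity exponent in `alpha ~ epsilon^beta`, in `[0, 2]`.
#' @param eta solvent viscosity (model units).
#' @param c_m dimensionless motor concentration.
#' @param c_p dimensionless passive crosslinker concentration.
#' @param alpha0 activity prefactor.
#' @return object of class `scaling_params`.
#' @export
scaling_params <- function(k0 = 0.001, kappa = 10 * k0, beta = 0.1, eta = 1,
                           c_m = 1, c_p = 0, alpha0 = 1) {
  if (k0 <= 0) stop("k0 must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  if (beta < 0 || beta > 2) stop("beta must lie in [0, 2]")
  if (eta <= 0) stop("eta must be > 0")
  if (c_p < 0) stop("c_p must be >= 0")
  structure(list(k0 = k0, kappa = kappa, beta = beta, eta = eta,
                 c_m = c_m, c_p = c_p, alpha0 = alpha0),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("scaling params: K0 = %g, kappa = %g (%.3g K0), beta = %g, eta = %g, c_p = %g\n",
              x$k0, x$kappa, x$kappa / x$k0, x$beta, x$eta, x$c_p))
  invisible(x)
}

#' Activity from the filament strain rate
#'
#' `alpha = alpha0 * epsilon^beta`.  With the working exponent
#' `beta = 0.1` the nematic activity grows slowly with the microscopic
#' strain rate; `beta = 0` gives constant activity and for `beta > 0`
#' activity vanishes with the strain rate.
#'
#' @param epsilon strain rate (normally normalized to its curve maximum so
#'   that `alpha <= alpha0`); must be >= 0.
#' @param beta activity exponent.
#' @param alpha0 prefactor.
#' @export
activity_from_strain <- function(epsilon, beta = 0.1, alpha0 = 1) {
  if (any(epsilon < 0)) stop("epsilon must be non-negative")
  alpha0 * epsilon^beta
}

#' Crosslink-augmented elastic constant
#'
#' `K = k0 + kappa * (c_m * p_cl + c_p)`; always at least `k0`.
#'
#' @param p_cl crosslink probability in `[0, 1]` (vectorized).
#' @param params a [scaling_params()].
#' @export
elastic_constant <- function(p_cl, params) {
  stopifnot(inherits(params, "scaling_params"))
  if (any(p_cl < 0 | p_cl > 1)) stop("p_cl must lie in [0, 1]")
  params$k0 + params$kappa * (params$c_m * p_cl + params$c_p)
}

#' Nematic speed and length scale from elasticity and activity
#'
#' Balancing the elastic stress `K / ell^2` against the active stress
#' `alpha` gives the nematic length `ell = sqrt(K / alpha)`; the dissipated
#' flow speed follows as `v = ell * alpha / eta = sqrt(K * alpha) / eta`.
#' Zero activity leaves `ell` undefined (returned `Inf`).
#'
#' @param K elastic constant (> 0, vectorized).
#' @param alpha activity (>= 0).
#' @param eta solvent viscosity.
#' @return list with components `v` and `ell`.
#' @export
hydrodynamic_prediction <- function(K, alpha, eta = 1) {
  if (any(K <= 0)) stop("K must be > 0")
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (eta <= 0) stop("eta must be > 0")
  ell <- ifelse(alpha == 0, Inf, sqrt(K / alpha))
  v <- sqrt(K * alpha) / eta
  list(v = v, ell = ell)
}

#' Hydrodynamic predictions over an ATP grid
#'
#' Composes [activity_from_strain()] (on the strain-rate curve normalized
#' to unit maximum), [elastic_constant()] (on the raw crosslink
#' probability) and [hydrodynamic_prediction()] pointwise over the grid of
#' a `microscopic_curves` table, and appends curves normalized to unit
#' maximum, matching how predictions are reported.
#'
#' @param micro a `microscopic_curves` table.
#' @param params a [scaling_params()].
#' @return data.frame of class `hydro_curves` with columns `atp`,
#'   `epsilon`, `p_cl`, `alpha`, `k_elastic`, `v`, `ell`, `v_norm`,
#'   `ell_norm`.
#' @export
predict_curves <- function(micro, params = scaling_params()) {
  stopifnot(inherits(micro, "microscopic_curves"))
  eps_max <- max(micro$epsilon)
  if (eps_max <= 0) stop("strain-rate curve is identically zero")
  alpha <- activity_from_strain(micro$epsilon / eps_max,
                                params$beta, params$alpha0)
  K <- elastic_constant(micro$p_cl, params)
  hp <- hydrodynamic_prediction(K, alpha, params$eta)
  out <- data.frame(atp = micro$atp, epsilon = micro$epsilon,
                    p_cl = micro$p_cl, alpha = alpha, k_elastic = K,
                    v = hp$v, ell = hp$ell)
  out$v_norm <- out$v / max(out$v)
  fin <- is.finite(out$ell)
  out$ell_norm <- out$ell / max(out$ell[fin])
  attr(out, "params") <- params
  class(out) <- c("hydro_curves", "data.frame")
  out
}

#' Locate the peak of the predicted nematic speed
#'
#' Finds the grid maximum of `v` and evaluates the stationarity residual of
#' `v = sqrt(K * alpha)` there: an interior maximum satisfies
#' `K' alpha + K alpha' = 0`, where primes are derivatives along the ATP
#' axis.  Derivatives are central finite differences with respect to
#' `log10([ATP])` on curves normalized to unit maximum, so the residual is
#' dimensionless and comparable across parameter sets.  Because `P_cl`
#' decreases with ATP, `K' <= 0` wherever the microscopic input behaves.
#'
#' @param curves a `hydro_curves` table (>= 3 grid points).
#' @return list of class `speed_peak`: `atp_peak`, `alpha_peak`,
#'   `residual`, `boundary_flag`, `k_prime_at_peak` (dK/dA, raw
#'   units), `flat_flag`, and the peak index.
#' @export
find_speed_peak <- function(curves) {
  stopifnot(inherits(curves, "hydro_curves"))
  n <- nrow(curves)
  if (n < 3) stop("need at least 3 grid points")
  v <- curves$v
  flat <- diff(range(v)) <= .Machine$double.eps * max(abs(v), 1)
  i <- which.max(v)  # ties: first (smallest ATP)
  boundary <- i == 1L || i == n
  x <- log10(curves$atp)
  Kn <- curves$k_elastic / max(curves$k_elastic)
  an <- curves$alpha / max(curves$alpha)
  cd <- function(f, j) (f[j + 1] - f[j - 1]) / (x[j + 1] - x[j - 1])
  residual <- if (boundary) NA_real_ else abs(cd(Kn, i) * an[i] + Kn[i] * cd(an, i))
  kp <- if (boundary) NA_real_ else
    (curves$k_elastic[i + 1] - curves$k_elastic[i - 1]) /
      (curves$atp[i + 1] - curves$atp[i - 1])
  structure(list(atp_peak = curves$atp[i], alpha_peak = curves$alpha[i],
                 residual = residual, boundary_flag = boundary,
                 k_prime_at_peak = kp, flat_flag = flat, index = i),
            class = "speed_peak")
}

#' @export
print.speed_peak <- function(x, ...) {
  cat(sprintf("speed peak at [ATP] = %.4g uM%s (residual %.3g)\n",
              x$atp_peak,
              if (x$boundary_flag) " [on grid boundary]" else "",
              x$residual))
  invisible(x)
}

#' Michaelis-Menten parameters for the phenomenological model
#'
#' Alternative microscopic input: motor speed saturating with ATP,
#' `v_m = v_max * A / (km_v + A)`, and crosslink probability decreasing
#' from `p_max` to `p_floor` with half-saturation `km_p`.  Defaults are
#' chosen so the resulting speed peak falls inside the 1-1000 uM window.
#'
#' @param v_max saturating motor speed (normalized units).
#' @param km_v half-saturation of the speed, uM.
#' @param p_max,p_floor crosslink probability bounds, `p_floor < p_max <= 1`.
#' @param km_p half-saturation of the unbinding, uM.
#' @export
mm_params <- function(v_max = 1, km_v = 50, p_max = 1, p_floor = 0.05,
                      km_p = 50) {
  if (any(c(v_max, km_v, p_max, p_floor, km_p) <= 0))
    stop("all Michaelis-Menten parameters must be positive")
  if (p_floor >= p_max || p_max > 1) stop("need p_floor < p_max <= 1")
  structure(list(v_max = v_max, km_v = km_v, p_max = p_max,
                 p_floor = p_floor, km_p = km_p), class = "mm_params")
}

#' Microscopic curves from the Michaelis-Menten model
#'
#' `v_m(A)` increases and `P_cl(A)` decreases with ATP; the extension rate
#' is approximated as `epsilon = v_m * P_cl`, which is non-monotonic in
#' ATP.  Feeding the result to [predict_curves()] with the default
#' parameters reproduces the non-monotonic speed and decreasing length.
#'
#' @param atp_grid ATP concentrations, uM.
#' @param params an [mm_params()].
#' @return a `microscopic_curves` table with the extra column
#'   `motor_velocity`.
#' @export
mm_microscopic_curves <- function(atp_grid, params = mm_params()) {
  stopifnot(inherits(params, "mm_params"))
  A <- atp_grid
  v_m <- params$v_max * A / (params$km_v + A)
  p_cl <- params$p_floor + (params$p_max - params$p_floor) *
    params$km_p / (params$km_p + A)
  df <- data.frame(atp = A, epsilon = v_m * p_cl, p_cl = p_cl,
                   motor_velocity = v_m)
  microscopic_curves(df, mm_params = params)
}
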