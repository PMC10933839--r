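#' Two-filament sweeps over ATP concentration
#'
#' Runs `reps` independent two-filament simulations at every point of an
#' ATP grid and collects the strain rate `epsilon` and crosslink
#' probability `p_cl` into a `microscopic_curves` table.  Replicate seeds
#' are derived from `seed` with a single counter over the whole sweep.
#'
#' @param cluster a [cluster_config()] (forced to two filaments).
#' @param rates a [rate_constants()].
#' @param atp_grid sorted positive ATP concentrations, uM.
#' @param reps replicates per grid point.
#' @param seed master seed.
#' @param t_max simulated time per trajectory, s.
#' @param normalize also store curves scaled to a maximum of exactly 1.
#' @return data.frame of class `microscopic_curves` with columns `atp`,
#'   `epsilon`, `p_cl`, `se_epsilon`, `se_p_cl` (and normalized columns if
#'   requested); normalization constants are kept as attributes.
#' @export
sweep_atp <- function(cluster, rates, atp_grid, reps = 100, seed = 1,
                      t_max = 100, normalize = FALSE) {
  if (length(atp_grid) == 0) stop("atp_grid must be non-empty")
  if (is.unsorted(atp_grid) || any(atp_grid <= 0))
    stop("atp_grid must be sorted ascending and positive")
  if (reps < 1) stop("reps must be >= 1")
  cl2 <- cluster_config(cluster$n_heads, cluster$step_size,
                        n_filaments = 2, c_m = cluster$c_m)
  seeds <- matrix(derive_seeds(seed, length(atp_grid) * reps),
                  nrow = length(atp_grid))
  rows <- lapply(seq_along(atp_grid), function(i) {
    trajs <- lapply(seeds[i, ], function(s)
      gillespie_trajectory(cl2, rates, atp_grid[i], t_max, s,
                           record_events = FALSE))
    st <- two_filament_summary(trajs, cl2)
    data.frame(atp = atp_grid[i], epsilon = st$epsilon, p_cl = st$p_cl,
               se_epsilon = st$se_epsilon, se_p_cl = st$se_p_cl)
  })
  out <- do.call(rbind, rows)
  out <- microscopic_curves(out, cluster = cl2, rates = rates)
  if (normalize) out <- normalize_curves(out)
  out
}

#' Construct a microscopic-curves table
#'
#' Container for `epsilon([ATP])` and `P_cl([ATP])`, produced by
#' [sweep_atp()], [mm_microscopic_curves()] or [synth_microscopic_curves()].
#'
#' @param df data.frame with at least `atp`, `epsilon`, `p_cl`.
#' @param ... metadata stored as attributes.
#' @export
microscopic_curves <- function(df, ...) {
  stopifnot(all(c("atp", "epsilon", "p_cl") %in% names(df)))
  if (is.unsorted(df$atp)) stop("atp grid must be sorted ascending")
  meta <- list(...)
  for (nm in names(meta)) attr(df, nm) <- meta[[nm]]
  attr(df, "normalized") <- isTRUE(attr(df, "normalized"))
  class(df) <- c("microscopic_curves", "data.frame")
  df
}

#' Normalize microscopic curves to unit maximum
#'
#' Adds `epsilon_norm` and `p_cl_norm` columns scaled so each curve's
#' maximum is exactly 1; the scale factors are stored as attributes
#' `epsilon_scale` and `p_cl_scale`.
#'
#' @param micro a `microscopic_curves` table.
#' @export
normalize_curves <- function(micro) {
  stopifnot(inherits(micro, "microscopic_curves"))
  es <- max(micro$epsilon); ps <- max(micro$p_cl)
  if (es <= 0 || ps <= 0) stop("cannot normalize curves with non-positive maxima")
  micro$epsilon_norm <- micro$epsilon / es
  micro$p_cl_norm <- micro$p_cl / ps
  attr(micro, "epsilon_scale") <- es
  attr(micro, "p_cl_scale") <- ps
  attr(micro, "normalized") <- TRUE
  micro
}

#' Default logarithmic ATP grid
#'
#' 40 log-spaced concentrations over 1 to 1000 uM, the range spanned by the
#' motility and nematic measurements.
#'
#' @param n grid points.
#' @param lo,hi range, uM.
#' @export
atp_grid_default <- function(n = 40, lo = 1, hi = 1000) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Smooth noisy microscopic curves
#'
#' Optional spline smoothing of stochastic `epsilon`/`p_cl` curves before
#' they are differentiated or searched for peaks; off by default
#' everywhere.  Each curve is fit by a smoothing spline in `log10([ATP])`
#' with `df` effective degrees of freedom, and the crosslink probability is
#' additionally projected onto the decreasing monotone cone (isotonic
#' regression) and clipped to `[0, 1]`.  The default `df = 5` is the
#' smallest basis that reproduces the deterministic Michaelis-Menten
#' backbone without displacing its speed peak.
#'
#' @param micro a `microscopic_curves` table.
#' @param df effective degrees of freedom of the smoothing spline.
#' @return the smoothed `microscopic_curves` table.
#' @export
smooth_microscopic_curves <- function(micro, df = 5) {
  stopifnot(inherits(micro, "microscopic_curves"))
  if (nrow(micro) <= df) stop("need more grid points than spline df")
  x <- log10(micro$atp)
  micro$epsilon <- pmax(1e-12,
    stats::predict(stats::smooth.spline(x, micro$epsilon, df = df), x)$y)
  p <- stats::predict(stats::smooth.spline(x, micro$p_cl, df = df), x)$y
  p <- -stats::isoreg(x, -p)$yf
  micro$p_cl <- pmin(1, pmax(0, p))
  attr(micro, "smoothed") <- TRUE
  micro
}
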