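#' Parameters of the synthetic vortex-field generator
#'
#' Describes a steady 2-D flow composed of azimuthal vortices of known core
#' radius -- a Rankine vortex (solid-body core, 1/r exterior; its maximum
#' speed sits exactly at the core radius, giving a sharp oracle for radius
#' estimators) or a Lamb-Oseen vortex (smooth; its maximum-speed radius is
#' computed numerically) -- plus i.i.d. additive Gaussian noise per frame.
#'
#' @param nx,ny grid size, px.
#' @param core_radius R, px (>= 2).
#' @param n_vortices number of vortices (0 gives a zero field).
#' @param profile `"rankine"` or `"lamb_oseen"`.
#' @param peak_speed maximum azimuthal speed, um/s.
#' @param sign_pattern `"alternating"` (checkerboard) or `"random"`.
#' @param noise_sigma noise standard deviation as a fraction of
#'   `peak_speed`.
#' @param pixel_size,frame_interval physical calibration.
#' @param n_frames frames (same base flow, independent noise).
#' @param seed integer seed.
#' @param placement `"lattice"` (tiled, allowed at any spacing) or
#'   `"random"` (rejection-sampled with centers >= 3 R apart; errors if
#'   impossible).
#' @return object of class `vortex_field_params`.
#' @export
vortex_field_params <- function(nx = 64, ny = 64, core_radius = 8,
                                n_vortices = 1,
                                profile = c("rankine", "lamb_oseen"),
                                peak_speed = 3,
                                sign_pattern = c("alternating", "random"),
                                noise_sigma = 0, pixel_size = 1,
                                frame_interval = 1, n_frames = 1, seed = 1,
                                placement = c("lattice", "random")) {
  profile <- match.arg(profile)
  sign_pattern <- match.arg(sign_pattern)
  placement <- match.arg(placement)
  if (core_radius < 2) stop("core_radius must be >= 2 px")
  if (n_vortices < 0) stop("n_vortices must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(nx = nx, ny = ny, core_radius = core_radius,
                 n_vortices = n_vortices, profile = profile,
                 peak_speed = peak_speed, sign_pattern = sign_pattern,
                 noise_sigma = noise_sigma, pixel_size = pixel_size,
                 frame_interval = frame_interval, n_frames = n_frames,
                 seed = as.integer(seed), placement = placement),
            class = "vortex_field_params")
}

# azimuthal speed profile, normalized to peak speed 1
.vortex_profile <- function(r, R, profile) {
  if (profile == "rankine") {
    ifelse(r <= R, r / R, R / r)
  } else {
    # Lamb-Oseen u_theta ~ (1 - exp(-(r/rc)^2)) / r, rescaled so the
    # numerically located maximum (near 1.121 rc) has unit speed
    f <- function(x) ifelse(x > 0, (1 - exp(-x^2)) / x, 0)
    xmax <- optimize(f, c(0.5, 3), maximum = TRUE)$maximum
    f(r / R) / f(xmax)
  }
}

#' Generate a synthetic vortex-structured velocity-field series
#'
#' Superposes the configured vortices on the grid and adds seeded Gaussian
#' noise independently per frame and component.  The ground-truth core
#' radius (px) is recorded as attribute `ground_truth_radius_px`; for
#' Lamb-Oseen vortices attribute `max_speed_radius_px` holds the
#' numerically located maximum-speed radius.
#'
#' @param params a [vortex_field_params()].
#' @return a [velocity_field_series()].
#' @export
synth_vortex_field <- function(params) {
  stopifnot(inherits(params, "vortex_field_params"))
  p <- params
  set.seed(p$seed)
  ux <- matrix(0, p$ny, p$nx)
  uy <- matrix(0, p$ny, p$nx)
  if (p$n_vortices > 0) {
    centers <- .place_vortices(p)
    xg <- matrix(seq_len(p$nx) - 0.5, p$ny, p$nx, byrow = TRUE)
    yg <- matrix(seq_len(p$ny) - 0.5, p$ny, p$nx)
    for (v in seq_len(nrow(centers))) {
      dx <- xg - centers$x[v]; dy <- yg - centers$y[v]
      r <- sqrt(dx^2 + dy^2)
      sp <- p$peak_speed * .vortex_profile(r, p$core_radius, p$profile)
      nz <- r > 0
      ux[nz] <- ux[nz] + centers$sign[v] * sp[nz] * (-dy[nz] / r[nz])
      uy[nz] <- uy[nz] + centers$sign[v] * sp[nz] * (dx[nz] / r[nz])
    }
  }
  aux <- array(0, c(p$ny, p$nx, p$n_frames))
  auy <- array(0, c(p$ny, p$nx, p$n_frames))
  sdn <- p$noise_sigma * p$peak_speed
  for (k in seq_len(p$n_frames)) {
    aux[, , k] <- ux + if (sdn > 0) rnorm(length(ux), 0, sdn) else 0
    auy[, , k] <- uy + if (sdn > 0) rnorm(length(uy), 0, sdn) else 0
  }
  out <- velocity_field_series(aux, auy, p$pixel_size, p$frame_interval)
  attr(out, "ground_truth_radius_px") <- p$core_radius
  attr(out, "params") <- p
  if (p$profile == "lamb_oseen") {
    f <- function(x) ifelse(x > 0, (1 - exp(-x^2)) / x, 0)
    attr(out, "max_speed_radius_px") <-
      p$core_radius * optimize(f, c(0.5, 3), maximum = TRUE)$maximum
  }
  out
}

.place_vortices <- function(p) {
  n <- p$n_vortices
  if (p$placement == "lattice") {
    k <- ceiling(sqrt(n))
    sx <- p$nx / k; sy <- p$ny / k
    grid <- expand.grid(i = seq_len(k), j = seq_len(k))[seq_len(n), ]
    sgn <- if (p$sign_pattern == "alternating") {
      (-1)^(grid$i + grid$j)
    } else {
      sample(c(-1, 1), n, replace = TRUE)
    }
    data.frame(x = (grid$i - 0.5) * sx, y = (grid$j - 0.5) * sy, sign = sgn)
  } else {
    minsep <- 3 * p$core_radius
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0
    while (length(xs) < n) {
      if (tries > 5000)
        stop("cannot place vortices without overlap (centers >= 3R apart)")
      cx <- runif(1, p$core_radius, p$nx - p$core_radius)
      cy <- runif(1, p$core_radius, p$ny - p$core_radius)
      if (all(sqrt((xs - cx)^2 + (ys - cy)^2) >= minsep)) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
      tries <- tries + 1
    }
    sgn <- if (p$sign_pattern == "alternating") {
      rep_len(c(1, -1), n)
    } else {
      sample(c(-1, 1), n, replace = TRUE)
    }
    data.frame(x = xs, y = ys, sign = sgn)
  }
}

#' Parameters for synthetic microscopic curves
#'
#' Deterministic Michaelis-Menten backbones (increasing strain-rate,
#' decreasing crosslink probability -- the structure the scaling analysis
#' assumes) with optional multiplicative log-normal noise.
#'
#' @param atp_grid ATP concentrations, uM.
#' @param mm an [mm_params()] backbone.
#' @param noise_sigma multiplicative noise scale (0 = deterministic).
#' @param seed integer seed.
#' @export
synthetic_curve_params <- function(atp_grid = atp_grid_default(),
                                   mm = mm_params(), noise_sigma = 0,
                                   seed = 1) {
  if (any(atp_grid <= 0) || is.unsorted(atp_grid))
    stop("atp_grid must be positive and ascending")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(atp_grid = atp_grid, mm = mm, noise_sigma = noise_sigma,
                 seed = as.integer(seed)), class = "synthetic_curve_params")
}

#' Generate synthetic microscopic curves
#'
#' Evaluates the Michaelis-Menten backbones on the grid and (optionally)
#' multiplies by independent log-normal factors `exp(sigma Z - sigma^2/2)`
#' (unit mean); the crosslink probability is clipped at 1.
#'
#' @param params a [synthetic_curve_params()].
#' @return a `microscopic_curves` table.
#' @export
synth_microscopic_curves <- function(params) {
  stopifnot(inherits(params, "synthetic_curve_params"))
  base <- mm_microscopic_curves(params$atp_grid, params$mm)
  if (params$noise_sigma > 0) {
    set.seed(params$seed)
    s <- params$noise_sigma
    lnoise <- function(n) exp(rnorm(n, 0, s) - s^2 / 2)
    base$epsilon <- base$epsilon * lnoise(nrow(base))
    base$p_cl <- pmin(1, base$p_cl * lnoise(nrow(base)))
  }
  attr(base, "synthetic_params") <- params
  base
}
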