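# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals they check.

# Replay a recorded event log in plain R, re-deriving anchor positions,
# displacement, sliding strain, crosslink time and run lengths from the
# stated rules.  Used to cross-check the C++ bookkeeping.
replay_trajectory <- function(tr, strain_establish = TRUE) {
  ev <- tr$events
  s <- tr$cluster$step_size
  nf <- tr$cluster$n_filaments
  n <- tr$cluster$n_heads
  bound_on <- rep(0L, n)            # 0 = unbound, else filament id
  pos <- rep(NA_real_, n)
  x <- c(0, 0)
  disp <- c(0, 0); strain <- 0; t_cl <- 0; t_bound <- 0
  in_run <- FALSE; run_start <- 0; runs <- numeric(0)
  t_prev <- 0
  crosslinked <- function() nf == 2 && any(bound_on == 1L) && any(bound_on == 2L)
  for (i in seq_len(nrow(ev))) {
    dt <- ev$t[i] - t_prev
    if (crosslinked()) t_cl <- t_cl + dt
    if (any(bound_on > 0L)) t_bound <- t_bound + dt
    t_prev <- ev$t[i]
    cl_before <- crosslinked()
    h <- ev$head[i]
    if (ev$transition[i] == 12) {
      bound_on[h] <- ev$filament[i]
      pos[h] <- ev$position[i]
    } else if (ev$transition[i] == 31) {
      bound_on[h] <- 0L
      pos[h] <- NA_real_
    }
    x_old <- x
    for (f in seq_len(nf))
      if (any(bound_on == f)) x[f] <- min(pos[bound_on == f]) + s / 2
    disp <- disp + (x - x_old)
    if (nf == 2) {
      count <- cl_before || (strain_establish && crosslinked())
      if (count) strain <- strain + sum(x - x_old)
    }
    any_now <- any(bound_on > 0L)
    if (!in_run && any_now) {
      in_run <- TRUE
      run_start <- if (nf == 2) sum(x) else x[1]
    } else if (in_run && !any_now) {
      in_run <- FALSE
      runs <- c(runs, (if (nf == 2) sum(x) else x[1]) - run_start)
    }
  }
  if (crosslinked()) t_cl <- t_cl + tr$t_final - t_prev
  if (any(bound_on > 0L)) t_bound <- t_bound + tr$t_final - t_prev
  if (in_run) runs <- c(runs, (if (nf == 2) sum(x) else x[1]) - run_start)
  list(displacement = disp, strain = strain, time_crosslinked = t_cl,
       time_bound = t_bound, run_lengths = runs)
}

# Exact crosslink probability by brute-force enumeration over head
# placements: each head independently unbound (1 - p), on filament A
# (p / 2), or on filament B (p / 2).
enum_crosslink_probability <- function(p, n) {
  states <- expand.grid(rep(list(0:2), n))
  w <- apply(states, 1, function(s) prod(c(1 - p, p / 2, p / 2)[s + 1]))
  both <- apply(states, 1, function(s) any(s == 1) && any(s == 2))
  sum(w[both])
}

# Dense-grid brute-force argmax of v = sqrt(K * alpha) for analytic
# activity / elasticity functions of ATP.
dense_peak_oracle <- function(alpha_fun, k_fun, lo = 1, hi = 1000, n = 1e4) {
  A <- 10^seq(log10(lo), log10(hi), length.out = n)
  A[which.max(sqrt(k_fun(A) * alpha_fun(A)))]
}

# Continuum oracle for the vorticity-velocity correlation radius: evaluates
# the correlation integral of the analytic azimuthal profile on a fine grid
# (independent of the package's estimator code path and resolution).
# Returns the radius (in units of the core radius) at which the azimuthally
# averaged response peaks.
oracle_correlation_radius <- function(profile = c("rankine", "lamb_oseen"),
                                      n = 512, half_width = 6) {
  profile <- match.arg(profile)
  h <- 2 * half_width / n
  x <- (seq_len(n) - n / 2 - 0.5) * h
  X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(x, n, n)
  r <- sqrt(X^2 + Y^2)
  ut <- if (profile == "rankine") ifelse(r <= 1, r, 1 / pmax(r, 1e-12))
        else (1 - exp(-r^2)) / pmax(r, 1e-12)
  ux <- ut * (-Y / pmax(r, 1e-12)); uy <- ut * (X / pmax(r, 1e-12))
  # vorticity by central differences (periodic), rows = y and cols = x
  dxuy <- (cbind(uy[, -1], uy[, 1]) - cbind(uy[, n], uy[, -n])) / (2 * h)
  dyux <- (rbind(ux[-1, ], ux[1, , drop = FALSE]) -
             rbind(ux[n, , drop = FALSE], ux[-n, ])) / (2 * h)
  om <- dxuy - dyux
  om <- om - mean(om); ux <- ux - mean(ux); uy <- uy - mean(uy)
  xc <- function(A, B) Re(fft(Conj(fft(A)) * fft(B), inverse = TRUE)) / length(A)
  Cx <- xc(om, ux); Cy <- xc(om, uy)
  ii <- c(0:(n / 2), (-n / 2 + 1):(-1))
  DX <- matrix(ii * h, n, n, byrow = TRUE); DY <- matrix(ii * h, n, n)
  rr <- sqrt(DX^2 + DY^2)
  az <- matrix(0, n, n); nz <- rr > 0
  az[nz] <- (-Cx[nz] * DY[nz] + Cy[nz] * DX[nz]) / rr[nz]
  bins <- seq(0, 4, by = 0.05)
  bi <- findInterval(rr[nz], bins)
  ok <- bi >= 1 & bi < length(bins)
  prof <- tapply(az[nz][ok], bi[ok], mean)
  rmid <- bins[as.integer(names(prof))] + 0.025
  rmid[which.max(prof)]
}

# Representative post-calibration rate constants for trend tests (the
# acceptance suite re-derives rates by the full scan; unit tests only need
# plausible kinetics with the right ATP structure).
test_rates <- function() rate_constants(430, 250, 4.3)
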