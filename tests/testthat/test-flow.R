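test_that("series construction validates shapes and finiteness", {
  ux <- matrix(1, 8, 8); uy <- matrix(0, 8, 8)
  s <- velocity_field_series(ux, uy, pixel_size = 0.26, frame_interval = 2)
  expect_equal(s$n_frames, 1)
  expect_error(velocity_field_series(matrix(1, 64, 64), matrix(1, 64, 63)),
               "incongruent")
  bad <- ux; bad[3, 3] <- NaN
  expect_error(velocity_field_series(bad, uy), "non-finite")
  expect_error(velocity_field_series(ux, uy, pixel_size = 0), "pixel_size")
})

test_that("write-then-read roundtrip preserves fields and metadata", {
  p <- vortex_field_params(nx = 24, ny = 16, core_radius = 4, n_vortices = 1,
                           noise_sigma = 0.05, n_frames = 3, seed = 3,
                           pixel_size = 0.26, frame_interval = 2)
  s <- synth_vortex_field(p)
  stem <- file.path(tempdir(), "fields")
  write_velocity_fields(s, stem)
  s2 <- load_velocity_fields(stem)
  expect_equal(s2$ux, s$ux, tolerance = 1e-12)
  expect_equal(s2$uy, s$uy, tolerance = 1e-12)
  expect_equal(s2$pixel_size, 0.26)
  expect_equal(s2$n_frames, 3)
  # mismatched component grids are a format error
  utils::write.table(matrix(0, 16, 23), paste0(stem, "_uy.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  expect_error(load_velocity_fields(stem), "format error")
})

test_that("flow speed implements the stated estimators", {
  u3 <- velocity_field_series(matrix(3, 8, 8), matrix(0, 8, 8))
  fs <- flow_speed(u3)
  expect_equal(fs$v_mean, 3)
  expect_equal(fs$v_rms, 3)

  mags <- matrix(c(1, 2, 3, 4), 2, 2)
  fs2 <- flow_speed(velocity_field_series(mags, matrix(0, 2, 2)))
  expect_equal(fs2$v_mean, 2.5)
  expect_equal(fs2$v_rms, 2.7386, tolerance = 1e-4)

  # homogeneity and the Jensen inequality
  p <- vortex_field_params(nx = 32, ny = 32, core_radius = 6,
                           noise_sigma = 0.1, seed = 4)
  s <- synth_vortex_field(p)
  f1 <- flow_speed(s)
  s3 <- velocity_field_series(3.7 * s$ux, 3.7 * s$uy)
  f3 <- flow_speed(s3)
  expect_equal(f3$v_mean, 3.7 * f1$v_mean, tolerance = 1e-12)
  expect_equal(f3$v_rms, 3.7 * f1$v_rms, tolerance = 1e-12)
  expect_gte(f1$v_rms, f1$v_mean)
})

test_that("direction autocorrelation behaves at its anchors", {
  # globally uniform direction: C = 1 everywhere, no crossing
  uni <- velocity_field_series(matrix(2, 32, 32), matrix(2, 32, 32))
  cu <- velocity_correlation_length(uni)
  expect_false(cu$crossed)
  expect_equal(cu$profile$c_uu, rep(1, nrow(cu$profile)), tolerance = 1e-12)

  # i.i.d. random directions: C(0) = 1, C(r > 0) ~ 0, crossing inside bin 1
  set.seed(9)
  th <- matrix(runif(64 * 64, 0, 2 * pi), 64, 64)
  iid <- velocity_field_series(cos(th), sin(th))
  ci <- velocity_correlation_length(iid)
  expect_equal(ci$profile$c_uu[1], 1)
  se <- 1 / sqrt(64 * 64)  # mean of ~N unit-vector dot products per bin
  expect_lt(max(abs(ci$profile$c_uu[-1])), 5 * se)
  expect_true(ci$crossed)
  expect_lte(ci$ell_corr, 1)
})

test_that("vorticity is exact for linear fields and right for a Rankine core", {
  n <- 21
  y <- matrix(rep(1:n, n), n, n); x <- t(y)
  om <- vorticity_field(list(ux = -0.1 * (y - 11), uy = 0.1 * (x - 11)))
  expect_equal(om[2:20, 2:20], matrix(0.2, 19, 19), tolerance = 1e-12)
  expect_equal(vorticity_field(list(ux = matrix(5, 8, 8), uy = matrix(2, 8, 8))),
               matrix(0, 8, 8))
  expect_error(vorticity_field(list(ux = matrix(1, 2, 2), uy = matrix(1, 2, 2))),
               "3 x 3")

  R <- 10; Om <- 3 / R
  s <- synth_vortex_field(vortex_field_params(nx = 64, ny = 64, core_radius = R,
                                              peak_speed = 3))
  w <- vorticity_field(s)
  ctr <- w[28:36, 28:36]                       # deep inside the core
  expect_equal(mean(ctr), 2 * Om, tolerance = 0.02)
  xg <- matrix(seq_len(64) - 0.5, 64, 64, byrow = TRUE)
  yg <- matrix(seq_len(64) - 0.5, 64, 64)
  rr <- sqrt((xg - 32)^2 + (yg - 32)^2)
  expect_lt(max(abs(w[rr > R + 2 & rr < 28])), 0.02 * 2 * Om)
})

test_that("vortex radius estimates match the continuum correlation oracle", {
  oracle <- oracle_correlation_radius("rankine")     # ~1.30 x core radius
  for (R in c(5, 12)) {
    s <- synth_vortex_field(vortex_field_params(
      nx = 96, ny = 96, core_radius = R, peak_speed = 3,
      noise_sigma = 0.05, n_frames = 5, seed = R))
    vl <- vortex_length(s)
    expect_lt(abs(vl$r_peak_px / (oracle * R) - 1), 0.15)
  }
  # uniform translation: zero vorticity is an error
  uni <- velocity_field_series(matrix(1, 32, 32), matrix(0.5, 32, 32))
  expect_error(vortex_length(uni), "vorticity")
})

test_that("vortex radius is invariant to uniform drift and 90-degree rotation", {
  s <- synth_vortex_field(vortex_field_params(
    nx = 64, ny = 64, core_radius = 8, n_vortices = 4,
    sign_pattern = "alternating", placement = "lattice",
    peak_speed = 3, noise_sigma = 0.05, n_frames = 3, seed = 21))
  base <- vortex_length(s)$r_peak_px
  drift <- velocity_field_series(s$ux + 1.3, s$uy - 0.4)
  expect_equal(vortex_length(drift)$r_peak_px, base, tolerance = 1e-10)
  # rotate the whole field by 90 degrees: (x,y) -> (-y,x), u -> (-uy, ux)
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  srot <- velocity_field_series(-rot(s$uy), rot(s$ux))
  expect_equal(vortex_length(srot)$r_peak_px, base, tolerance = 1e-8)
})

test_that("lengths scale with the pixel size", {
  p <- vortex_field_params(nx = 48, ny = 48, core_radius = 6, n_vortices = 4,
                           placement = "lattice", noise_sigma = 0.05,
                           n_frames = 2, seed = 5)
  s1 <- synth_vortex_field(p)
  s2 <- velocity_field_series(s1$ux, s1$uy, pixel_size = 0.26)
  expect_equal(vortex_length(s2)$ell_vort, 0.26 * vortex_length(s1)$ell_vort,
               tolerance = 1e-12)
  expect_equal(velocity_correlation_length(s2)$ell_corr,
               0.26 * velocity_correlation_length(s1)$ell_corr,
               tolerance = 1e-12)
})

test_that("frame-set variability partitions frames as stated", {
  # engineer per-set mean speeds 1..5 over 5 sets of 5 frames
  ux <- array(rep(1:5, each = 8 * 8 * 5), c(8, 8, 25))
  s <- velocity_field_series(ux, array(0, c(8, 8, 25)))
  v <- frame_set_variability(s, function(x) flow_speed(x)$v_mean)
  expect_equal(as.numeric(v), 1.5811, tolerance = 1e-4)
  expect_equal(attr(v, "estimates"), 1:5, tolerance = 1e-12)

  # identical frames: zero variability
  su <- velocity_field_series(array(2, c(8, 8, 25)), array(1, c(8, 8, 25)))
  expect_equal(as.numeric(frame_set_variability(su, function(x) flow_speed(x)$v_rms)), 0)

  s24 <- velocity_field_series(array(1, c(8, 8, 24)), array(0, c(8, 8, 24)))
  expect_error(frame_set_variability(s24, function(x) flow_speed(x)$v_mean),
               "at least 25")
})
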