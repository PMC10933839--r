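make_hydro <- function(atp, alpha, K, eta = 1) {
  out <- data.frame(atp = atp, epsilon = NA, p_cl = NA, alpha = alpha,
                    k_elastic = K, v = sqrt(K * alpha) / eta,
                    ell = sqrt(K / alpha))
  out$v_norm <- out$v / max(out$v)
  out$ell_norm <- out$ell / max(out$ell)
  class(out) <- c("hydro_curves", "data.frame")
  out
}

test_that("activity, elasticity and force balance evaluate exactly", {
  expect_equal(activity_from_strain(1, beta = 0.1), 1)
  expect_equal(activity_from_strain(c(0.2, 0.7), beta = 0), c(1, 1))
  expect_equal(activity_from_strain(0.5, beta = 0.1), 0.9330, tolerance = 1e-4)
  expect_error(activity_from_strain(-0.1), "non-negative")

  p <- scaling_params(k0 = 0.001, kappa = 0.01)
  expect_equal(elastic_constant(0.43, p), 0.0053)
  expect_equal(elastic_constant(0, scaling_params(k0 = 0.001, kappa = 0.01, c_p = 0)),
               0.001)
  expect_equal(elastic_constant(0.9, scaling_params(k0 = 0.001, kappa = 0)), 0.001)

  hp <- hydrodynamic_prediction(0.004, 0.01, eta = 1)
  expect_equal(hp$ell, 0.632456, tolerance = 1e-5)
  expect_equal(hp$v, 0.00632456, tolerance = 1e-6)
  expect_equal(hydrodynamic_prediction(0.25, 0.25)$ell, 1)
  expect_identical(hydrodynamic_prediction(1, 0)$ell, Inf)
})

test_that("scaling identities hold on every grid point", {
  A <- atp_grid_default()
  h <- predict_curves(mm_microscopic_curves(A), scaling_params())
  expect_equal(h$v, h$ell * h$alpha / 1, tolerance = 1e-12)
  # sqrt homogeneity: doubling K scales ell by sqrt(2)
  expect_equal(hydrodynamic_prediction(2 * h$k_elastic, h$alpha)$ell / h$ell,
               rep(sqrt(2), length(A)), tolerance = 1e-12)
  expect_equal(max(h$v_norm), 1)
  expect_equal(max(h$ell_norm), 1)
})

test_that("speed-peak location matches the dense brute-force oracle", {
  a_fun <- function(A) A / (A + 50)
  k_fun <- function(A) 1 + 450 / (A + 50)
  A <- atp_grid_default(n = 60)
  pk <- find_speed_peak(make_hydro(A, a_fun(A), k_fun(A)))
  oracle <- dense_peak_oracle(a_fun, k_fun)
  step <- max(A[-1] / A[-length(A)])
  expect_false(pk$boundary_flag)
  expect_lt(abs(log(pk$atp_peak / oracle)), log(step) * 1.0001)
})

test_that("boundary and flat speed curves are flagged", {
  A <- atp_grid_default(n = 10)
  up <- make_hydro(A, A / (A + 50), rep(1, 10))
  pk <- find_speed_peak(up)
  expect_true(pk$boundary_flag)
  expect_equal(pk$atp_peak, max(A))
  flat <- make_hydro(A, rep(0.5, 10), rep(1, 10))
  pkf <- find_speed_peak(flat)
  expect_true(pkf$flat_flag)
  expect_equal(pkf$atp_peak, A[1])
  expect_error(find_speed_peak(make_hydro(A[1:2], c(1, 2), c(1, 1))), "3 grid")
})

test_that("stationarity residual vanishes at an interior peak on refined grids", {
  A <- atp_grid_default(n = 2001)
  h <- predict_curves(mm_microscopic_curves(A), scaling_params())
  pk <- find_speed_peak(h)
  expect_false(pk$boundary_flag)
  expect_lt(pk$residual, 1e-3)
  expect_lte(pk$k_prime_at_peak, 0)  # P_cl decreases, so K' <= 0
})

test_that("Michaelis-Menten curves have the stated structure and limits", {
  p <- mm_params()
  mc <- mm_microscopic_curves(c(1, 10, 100, 1e9), p)
  expect_equal(mc$motor_velocity[4], p$v_max, tolerance = 1e-6)
  expect_equal(mc$p_cl[4], p$p_floor, tolerance = 1e-4)
  A <- atp_grid_default(n = 50)
  mc2 <- mm_microscopic_curves(A, p)
  expect_true(all(diff(mc2$motor_velocity) > 0))
  expect_true(all(diff(mc2$p_cl) < 0))
  # epsilon has an interior maximum; coarse argmax within one step of dense
  eps_fun <- function(A) (p$v_max * A / (p$km_v + A)) *
    (p$p_floor + (p$p_max - p$p_floor) * p$km_p / (p$km_p + A))
  dense <- 10^seq(0, 3, length.out = 1e4)
  A_star <- dense[which.max(eps_fun(dense))]
  step <- max(A[-1] / A[-length(A)])
  expect_lt(abs(log(A[which.max(mc2$epsilon)] / A_star)), log(step) * 1.0001)
})

test_that("crosslink-augmented elasticity bends the speed curve as expected", {
  A <- atp_grid_default(n = 200)
  mm <- mm_microscopic_curves(A)

  # kappa = 10 K0, beta = 0.1: interior maximum in v, ell decreasing
  pk10 <- find_speed_peak(predict_curves(mm, scaling_params()))
  expect_false(pk10$boundary_flag)
  h10 <- predict_curves(mm, scaling_params())
  expect_true(all(diff(h10$ell) < 0))

  # larger kappa moves the peak to lower ATP
  pk5 <- find_speed_peak(predict_curves(mm, scaling_params(kappa = 0.005)))
  pk20 <- find_speed_peak(predict_curves(mm, scaling_params(kappa = 0.02)))
  expect_lte(pk20$atp_peak, pk10$atp_peak)
  expect_lte(pk10$atp_peak, pk5$atp_peak)

  # passive crosslinker moves the peak to higher ATP and lengthens ell
  hcp <- predict_curves(mm, scaling_params(c_p = 0.5))
  expect_gte(find_speed_peak(hcp)$atp_peak, pk10$atp_peak)
  expect_true(all(hcp$ell > h10$ell))
})

test_that("a large activity exponent restores monotone speed", {
  # monotone strain-rate input, crosslinking decreasing to a floor high
  # enough that activity growth can outrun the elasticity loss at beta = 1
  A <- atp_grid_default(n = 100)
  micro <- microscopic_curves(data.frame(
    atp = A, epsilon = (A / (A + 50))^2,
    p_cl = 0.3 + 0.7 * 50 / (50 + A)))
  expect_false(all(diff(predict_curves(micro, scaling_params(beta = 0.1))$v) > 0))
  expect_true(all(diff(predict_curves(micro, scaling_params(beta = 1))$v) > 0))
})

test_that("parameter validation rejects out-of-range scaling inputs", {
  expect_error(scaling_params(k0 = 0), "k0")
  expect_error(scaling_params(beta = 3), "beta")
  expect_error(elastic_constant(1.3, scaling_params()), "\\[0, 1\\]")
  expect_error(mm_params(p_floor = 0.9, p_max = 0.5), "p_floor")
})
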