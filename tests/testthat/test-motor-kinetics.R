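test_that("degenerate inputs behave as the cycle dictates", {
  cl <- cluster_config(3)
  r <- rate_constants(10, 10, 0.1)

  # no time elapses: no events, all heads unbound with ATP
  tr0 <- gillespie_trajectory(cl, r, atp = 100, t_max = 0, seed = 1)
  expect_equal(nrow(tr0$events), 0)
  expect_equal(tr0$final_state, rep(1L, 3))

  # zero ATP: unbinding rate is zero, heads park in rigor forever
  trr <- gillespie_trajectory(cl, r, atp = 0, t_max = 50, seed = 2)
  expect_equal(trr$final_state, rep(3L, 3))
  expect_false(any(trr$events$transition == 31))

  expect_error(gillespie_trajectory(cl, r, atp = -1, t_max = 1, seed = 1),
               "non-negative")
  expect_error(rate_constants(0, 1, 1), "positive")
  expect_error(cluster_config(0), "n_heads")
})

test_that("event logs obey the trajectory invariants", {
  cl <- cluster_config(4, n_filaments = 2)
  tr <- gillespie_trajectory(cl, rate_constants(5, 8, 2), atp = 2,
                             t_max = 50, seed = 11)
  ev <- tr$events
  expect_true(all(diff(ev$t) > 0))
  # per head, transitions cycle 12 -> 23 -> 31 -> 12 with no other order
  nxt <- c("12" = 23, "23" = 31, "31" = 12)
  for (h in unique(ev$head)) {
    seq_h <- ev$transition[ev$head == h]
    expect_equal(seq_h[1], 12)
    expect_true(all(seq_h[-1] == nxt[as.character(seq_h[-length(seq_h)])]))
  }
  # binding positions only on 1 -> 2
  expect_true(all(is.finite(ev$position[ev$transition == 12])))
  expect_true(all(is.na(ev$position[ev$transition != 12])))
})

test_that("identical seeds give bit-identical trajectories", {
  cl <- cluster_config(4, n_filaments = 2)
  r <- rate_constants(5, 8, 2)
  a <- gillespie_trajectory(cl, r, 2, 20, seed = 99)
  b <- gillespie_trajectory(cl, r, 2, 20, seed = 99)
  expect_identical(a$events, b$events)
  expect_identical(a$strain, b$strain)
  expect_false(identical(
    a$events, gillespie_trajectory(cl, r, 2, 20, seed = 100)$events))
})

test_that("completed cycle count matches the renewal oracle", {
  # mean cycle time 3 s => ~333 cycles in 1000 s; renewal CLT sd = 10.5
  tr <- gillespie_trajectory(cluster_config(1), rate_constants(1, 1, 1),
                             atp = 1, t_max = 1000, seed = 42)
  n_cycles <- sum(tr$events$transition == 31)
  se <- sqrt(1000 * 3 / 27)
  expect_lt(abs(n_cycles - 1000 / 3), 3 * se)
})

test_that("per-state holding times are exponential with the configured rates", {
  rates <- c(`12` = 10, `23` = 20, `31` = 5)
  tr <- gillespie_trajectory(cluster_config(1), rate_constants(10, 20, 5),
                             atp = 1, t_max = 3600, seed = 5)
  ev <- tr$events
  # duration spent in the state that each transition terminates
  start_t <- c(0, ev$t[-nrow(ev)])
  dur <- ev$t - start_t
  for (tier in c("12", "23", "31")) {
    d <- dur[ev$transition == as.integer(tier)]
    expect_gt(length(d), 1e4)
    expect_gt(stats::ks.test(d, "pexp", rate = rates[tier])$p.value, 0.01)
  }
})

test_that("C++ bookkeeping agrees with an independent R replay of the events", {
  for (nf in 1:2) {
    cl <- cluster_config(3, n_filaments = nf)
    tr <- gillespie_trajectory(cl, rate_constants(4, 6, 1.5), atp = 2,
                               t_max = 40, seed = 20 + nf)
    rp <- replay_trajectory(tr)
    expect_equal(tr$displacement[seq_len(nf)], rp$displacement[seq_len(nf)],
                 tolerance = 1e-10)
    expect_equal(tr$time_bound, rp$time_bound, tolerance = 1e-10)
    expect_equal(sort(tr$run_lengths), sort(rp$run_lengths), tolerance = 1e-10)
    if (nf == 2) {
      expect_equal(tr$strain, rp$strain, tolerance = 1e-10)
      expect_equal(tr$time_crosslinked, rp$time_crosslinked, tolerance = 1e-10)
    }
  }
  # and the stricter strain convention replays identically too
  cl <- cluster_config(3, n_filaments = 2)
  tr <- gillespie_trajectory(cl, rate_constants(4, 6, 1.5), atp = 2,
                             t_max = 40, seed = 31, strain_establish = FALSE)
  expect_equal(tr$strain, replay_trajectory(tr, strain_establish = FALSE)$strain,
               tolerance = 1e-10)
})

test_that("ensemble summaries implement the stated estimators", {
  cl <- cluster_config(4)
  trajs <- simulate_ensemble(cl, rate_constants(50, 80, 1), atp = 20,
                             t_max = 30, reps = 5, seed = 3)
  st <- single_filament_summary(trajs, cl)
  expect_equal(st$velocity,
               sum(vapply(trajs, function(x) x$displacement[1], 0)) /
                 sum(vapply(trajs, function(x) x$t_final, 0)))
  expect_equal(st$run_length,
               mean(unlist(lapply(trajs, function(x) x$run_lengths))))
  expect_error(single_filament_summary(list(), cl), "empty")

  # ensemble in which no head ever binds (t_max = 0 trajectories)
  empty <- simulate_ensemble(cl, rate_constants(50, 80, 1), 20,
                             t_max = 0, reps = 3, seed = 4)
  st0 <- single_filament_summary(empty, cl)
  expect_true(st0$no_binding)
  expect_equal(st0$n_runs, 0)
  expect_equal(st0$run_length, 0)
})

test_that("a single head can never crosslink two filaments", {
  cl <- cluster_config(1, n_filaments = 2)
  trajs <- simulate_ensemble(cl, rate_constants(10, 10, 1), atp = 5,
                             t_max = 50, reps = 5, seed = 8)
  st <- two_filament_summary(trajs, cl)
  expect_identical(st$p_cl, 0)
  expect_identical(st$epsilon, 0)
})

test_that("valency reduces single-filament speed and increases processivity", {
  r <- test_rates()
  stats_n <- lapply(c(3, 8), function(n) {
    cl <- cluster_config(n)
    single_filament_summary(
      simulate_ensemble(cl, r, atp = 100, t_max = 40, reps = 25, seed = 2), cl)
  })
  expect_gt(stats_n[[1]]$velocity, stats_n[[2]]$velocity)
  expect_lt(stats_n[[1]]$run_length, stats_n[[2]]$run_length)
})

test_that("higher valency crosslinks more at every ATP tested", {
  r <- test_rates()
  for (atp in c(5, 50, 500)) {
    p3 <- two_filament_summary(
      simulate_ensemble(cluster_config(3, n_filaments = 2), r, atp,
                        t_max = 40, reps = 15, seed = 6),
      cluster_config(3, n_filaments = 2))$p_cl
    p8 <- two_filament_summary(
      simulate_ensemble(cluster_config(8, n_filaments = 2), r, atp,
                        t_max = 40, reps = 15, seed = 6),
      cluster_config(8, n_filaments = 2))$p_cl
    expect_gte(p8, p3)
  }
})

test_that("ATP sweeps produce the expected monotone structure", {
  r <- test_rates()
  grid <- atp_grid_default(n = 8)
  mc <- sweep_atp(cluster_config(4), r, grid, reps = 12, seed = 2,
                  t_max = 30, normalize = TRUE)
  expect_equal(max(mc$epsilon_norm), 1)
  expect_equal(max(mc$p_cl_norm), 1)
  expect_gt(cor(grid, mc$epsilon, method = "spearman"), 0.9)
  expect_lt(cor(grid, mc$p_cl, method = "spearman"), -0.9)
  expect_error(sweep_atp(cluster_config(4), r, numeric(0)), "non-empty")
  expect_error(sweep_atp(cluster_config(4), r, c(5, 1)), "sorted")
  # determinism of the whole sweep
  mc2 <- sweep_atp(cluster_config(4), r, grid, reps = 12, seed = 2,
                   t_max = 30, normalize = TRUE)
  expect_identical(mc$epsilon, mc2$epsilon)
})
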