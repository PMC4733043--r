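FIG1_RATES <- model_rates(2, 0.9, 1, 0.02)

test_that("identical configuration and seed reproduce runs exactly", {
  cfg <- simulation_config(FIG1_RATES, n0 = 0, t_end = 20, seed = 42)
  t1 <- simulate_trajectory(cfg)
  t2 <- simulate_trajectory(cfg)
  expect_identical(t1$time, t2$time)
  expect_identical(t1$count, t2$count)
  s1 <- simulate_ensemble(cfg, 500, tau = 5)
  s2 <- simulate_ensemble(cfg, 500, tau = 5)
  expect_identical(s1$counts, s2$counts)
  # a different seed gives a different run
  t3 <- simulate_trajectory(simulation_config(FIG1_RATES, n0 = 0, t_end = 20,
                                              seed = 43))
  expect_false(identical(t1$time, t3$time))
})

test_that("trajectories are valid birth-death paths", {
  for (scheme in c("event_driven", "fixed_step")) {
    cfg <- simulation_config(FIG1_RATES, n0 = 3, t_end = 10, dt = 1e-3,
                             seed = 7, scheme = scheme)
    traj <- simulate_trajectory(cfg)
    expect_identical(traj$count[1], 3L)
    expect_true(all(traj$count >= 0))
    expect_true(all(abs(diff(traj$count)) == 1L))
    expect_true(!is.unsorted(traj$time))
  }
})

test_that("a cell in an absorbing state never moves", {
  # decay-only model starting empty: no process can fire
  cfg <- simulation_config(model_rates(0, 0, 1, 0), n0 = 0, t_end = 50,
                           seed = 1)
  traj <- simulate_trajectory(cfg)
  expect_identical(traj$count, 0L)
  # pure fusion from a single organelle: fusion needs a pair
  cfg2 <- simulation_config(model_rates(0, 0, 0, 0.5), n0 = 1, t_end = 50,
                            seed = 1)
  expect_identical(simulate_trajectory(cfg2)$count, 1L)
})

test_that("an ensemble observed at tau = 0 sits at its initial count", {
  cfg <- simulation_config(FIG1_RATES, n0 = 4, t_end = 1, seed = 5)
  snap <- simulate_ensemble(cfg, 200, tau = 0)
  expect_identical(snap$n, 4L)
  expect_identical(snap$cells, 200L)
})

test_that("time averages from either starting point settle near the equilibrium mean", {
  ref <- distribution_stats(stationary_distribution(FIG1_RATES))
  for (n0 in c(0L, 50L)) {
    cfg <- simulation_config(FIG1_RATES, n0 = n0, t_end = 4000, seed = 17 + n0)
    st <- trajectory_stats(simulate_trajectory(cfg))
    # correlation-time-aware Monte Carlo tolerance (tau_c ~ 1/gamma = 1)
    expect_equal(st$mean, ref$mean, tolerance = 0.1)
  }
})

test_that("long equilibrated runs reproduce the exact mean and Fano factor", {
  r <- model_rates(2, 0.5, 1, 0)  # mean 4, Fano 2 exactly
  cfg <- simulation_config(r, n0 = 0, t_end = 8000, seed = 23)
  st <- trajectory_stats(simulate_trajectory(cfg))
  # SE of the time-averaged mean ~ sqrt(2 * tau_c * var / T) ~ 0.05
  expect_equal(st$mean, peroxisome_mean(r), tolerance = 0.08)
  expect_equal(st$fano, peroxisome_fano(r), tolerance = 0.1)
})

test_that("time-average and ensemble-average sampling agree at equilibrium", {
  cfg <- simulation_config(FIG1_RATES, n0 = 1, t_end = 3000, seed = 31)
  st_time <- trajectory_stats(simulate_trajectory(cfg))
  snap <- simulate_ensemble(cfg, 5000, tau = 25)
  st_ens <- observed_moments(snap)
  expect_equal(st_time$mean, st_ens$mean, tolerance = 0.15)
  expect_equal(st_time$fano, st_ens$fano, tolerance = 0.25)
})

test_that("fixed-step and event-driven ensembles agree within sampling error", {
  n_cells <- 2000
  tau <- 5
  ev <- simulate_ensemble(simulation_config(FIG1_RATES, n0 = 1, t_end = tau,
                                            seed = 101), n_cells, tau)
  fs <- simulate_ensemble(simulation_config(FIG1_RATES, n0 = 1, t_end = tau,
                                            seed = 202, scheme = "fixed_step",
                                            dt = 1e-4), n_cells, tau)
  m_ev <- observed_moments(ev)
  m_fs <- observed_moments(fs)
  # two independent Monte Carlo estimates of the same mean
  se <- sqrt(m_ev$variance / n_cells + m_fs$variance / n_cells)
  expect_lt(abs(m_ev$mean - m_fs$mean), 4 * se)
  # and the two histograms are close in total variation (two independent
  # 2000-cell samples over ~20 bins carry ~0.05 of TV sampling noise alone)
  all_n <- 0:max(ev$counts, fs$counts)
  h_ev <- tabulate(ev$counts + 1L, length(all_n)) / n_cells
  h_fs <- tabulate(fs$counts + 1L, length(all_n)) / n_cells
  expect_lt(0.5 * sum(abs(h_ev - h_fs)), 0.1)
})

test_that("the divergence guard aborts runaway fission runs", {
  r <- model_rates(2, 1.1, 1, 0)
  expect_false(classify_regime(r)$has_limiting_distribution)
  cfg <- simulation_config(r, n0 = 10, t_end = 1e4, seed = 3,
                           divergence_cap = 1e4)
  err <- tryCatch(simulate_trajectory(cfg), error = identity)
  expect_s3_class(err, "orgdist_divergence_error")
  expect_match(conditionMessage(err), "FISSION_EXCEEDS_DECAY")
  err2 <- tryCatch(simulate_ensemble(cfg, 5, tau = 1e4), error = identity)
  expect_s3_class(err2, "orgdist_divergence_error")
})

test_that("fixed-step simulation refuses a step size that breaks first order", {
  cfg <- simulation_config(model_rates(2, 0.9, 1, 0.02), n0 = 50,
                           t_end = 1, dt = 0.5, seed = 1,
                           scheme = "fixed_step")
  expect_error(simulate_trajectory(cfg), "reduce dt")
})

test_that("ensembles converge to the solver's limiting distribution", {
  dist <- stationary_distribution(FIG1_RATES)
  cfg <- simulation_config(FIG1_RATES, n0 = 1, t_end = 15, seed = 57)
  taus <- c(0.2, 1.0, 5.0, 15.0)
  tvs <- vapply(taus, function(tau) {
    snapshot_tv_distance(simulate_ensemble(cfg, 4000, tau), dist)
  }, numeric(1))
  # distance to equilibrium shrinks with observation time (up to MC noise)
  expect_true(all(diff(tvs) < 0.02))
  expect_lt(tvs[length(tvs)], 0.05)
  expect_gt(tvs[1], 0.5)
})
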