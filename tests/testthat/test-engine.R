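test_that("configuration validation catches domain violations", {
  expect_error(simulation_config(b = 1.5, alpha = 1.2), "alpha")
  expect_error(simulation_config(b = 1.5, k_noise = 0), "k_noise")
  expect_error(simulation_config(b = 1.5, n = 100, mcs_total = 10,
                                 window = 11), "window")
  expect_error(simulation_config(b = 2.5), "b")
  cfg <- simulation_config(b = 1.5, n = 100, mcs_total = 10, window = 10,
                           realizations = 1)
  expect_s3_class(cfg, "simulation_config")
  expect_identical(cfg$utility_convention, "additive")
})

test_that("accumulated payoff sums row-player payoffs over same-layer neighbours", {
  star <- star_topology(4)
  cfg <- tiny_config(4, b = 1.8)
  # layer-1 defector surrounded by three cooperators earns 3 b
  st <- manual_state(star, star, s1 = c(1, 0, 0, 0), s2 = rep(2, 4), cfg)
  expect_equal(accumulated_payoff(st, 1, 1), 3 * 1.8)
  expect_equal(accumulated_payoff(st, 1, 2), 0)  # C against the D centre
  # layer-2 Q with neighbours {D, Q} at gamma = pi/2, b = 2 earns b + 1
  p3 <- path_topology(3)
  cfg2 <- tiny_config(3, b = 2, gamma = pi / 2)
  st2 <- manual_state(p3, p3, s1 = c(0, 0, 0),
                      s2 = strategy_code(c("D", "Q", "Q")), cfg2)
  expect_equal(accumulated_payoff(st2, 2, 2), 2 + 1)
  # isolated node in a custom graph earns the empty sum
  iso <- qpdnet:::new_topology(3L, cbind(1L, 2L))
  st3 <- manual_state(iso, iso, s1 = c(1, 0, 0), s2 = c(2, 0, 1), cfg2)
  expect_equal(accumulated_payoff(st3, 1, 3), 0)
})

test_that("utility conventions combine own and partner payoffs as stated", {
  # alpha = 0: completely independent layers under either convention
  expect_equal(utility(2, 4, 0), 2)
  expect_equal(utility(2, 4, 0, convention = "convex"), 2)
  expect_equal(utility(2, 4, 0.5, convention = "convex"), 3)
  expect_equal(utility(2, 4, 1, convention = "convex"), 4)
  expect_equal(utility(2, 4, 1, convention = "additive"), 6)
  expect_error(utility(1, 1, -0.1), "alpha")
})

test_that("Fermi adoption probability has the closed form and saturates safely", {
  expect_equal(fermi_adopt_prob(1, 1, 0.1), 0.5)
  expect_equal(fermi_adopt_prob(0, 0.1, 0.1), 1 / (1 + exp(-1)))
  expect_equal(fermi_adopt_prob(0, 0.1, 0.1), 0.731059, tolerance = 1e-6)
  # increasing in the neighbour's utility advantage
  d <- fermi_adopt_prob(0, seq(-3, 3, 0.5), 0.1)
  expect_true(all(diff(d) > 0))
  # saturation without numeric error
  expect_equal(fermi_adopt_prob(100, 0, 0.1), 0)
  expect_equal(fermi_adopt_prob(0, 100, 0.1), 1)
  expect_false(any(is.nan(fermi_adopt_prob(c(1e8, -1e8), 0, 0.1))))
  expect_error(fermi_adopt_prob(1, 1, 0), "k_noise")
})

test_that("an elementary event changes at most one node and respects adoption", {
  p2 <- path_topology(2)
  cfg <- tiny_config(2, b = 1.5, alpha = 0)
  st <- manual_state(p2, p2, s1 = c(0, 1), s2 = c(0, 1), cfg)
  # the C node adopts D with probability 1/(1+exp((0 - 1.5)/0.1)): near 1
  p_adopt <- fermi_adopt_prob(accumulated_payoff(st, 1, 1),
                              accumulated_payoff(st, 1, 2), 0.1)
  expect_equal(p_adopt, 1 / (1 + exp(-15)))
  expect_equal(1 - p_adopt, 3.06e-7, tolerance = 0.01)
  set.seed(1)
  for (i in 1:20) {
    nxt <- elementary_step(st, 1L)
    expect_lte(sum(nxt$strategies1 != st$strategies1), 1L)
  }
  # identical strategies: state unchanged regardless of the adoption draw
  same <- manual_state(p2, p2, s1 = c(1, 1), s2 = c(2, 2), cfg)
  set.seed(2)
  for (i in 1:10)
    expect_identical(elementary_step(same, 1L)$strategies1, c(1L, 1L))
})

test_that("one MCS performs n updates per layer and monomorphic states absorb", {
  p6 <- path_topology(6)
  cfg <- tiny_config(6, b = 1.8, gamma = pi / 3, alpha = 0.5)
  st <- manual_state(p6, p6, s1 = rep(1, 6), s2 = rep(1, 6), cfg)
  set.seed(3)
  out <- st
  for (i in 1:5) out <- monte_carlo_step(out)
  # all-D is absorbing on both layers (imitation cannot innovate)
  expect_identical(out$strategies1, rep(1L, 6))
  expect_identical(out$strategies2, rep(1L, 6))
  expect_identical(out$mcs_index, 5L)
  # compiled sampler agrees: a monomorphic state is a point mass on itself
  freq <- sample_step_frequencies(st, 2L, 1e4, seed = 4)
  expect_equal(unname(freq[["none"]]), 1)
})

test_that("strategies absent from a layer never reappear (no innovation)", {
  p8 <- path_topology(8)
  cfg <- tiny_config(8, b = 1.3, gamma = pi / 2, alpha = 0.7)
  # no Q anywhere on layer 2
  st <- manual_state(p8, p8, s1 = rep(c(0, 1), 4), s2 = rep(c(0, 1), 4), cfg)
  set.seed(5)
  for (i in 1:10) {
    st <- monte_carlo_step(st)
    expect_false(any(st$strategies2 == 2L))
    expect_true(all(st$strategies1 %in% c(0L, 1L)))
  }
})

test_that("simulate_coupled honours the initialization contract at mcs_total = 0", {
  cfg <- simulation_config(b = 1.5, gamma = pi / 4, alpha = 0.3, n = 2000,
                           mcs_total = 0, window = 1, realizations = 1,
                           seed = 7)
  traj <- simulate_coupled(cfg)
  expect_equal(nrow(traj), 1L)
  # binomial/multinomial fluctuation at n = 2000: sd ~ 0.011
  expect_equal(traj$rho_C_1, 0.5, tolerance = 0.12)
  expect_equal(traj$rho_C_2, 1 / 3, tolerance = 0.15)
  expect_equal(traj$rho_Q_2, 1 / 3, tolerance = 0.15)
  expect_equal(traj$rho_C_1 + traj$rho_D_1, 1)
  expect_equal(traj$rho_C_2 + traj$rho_D_2 + traj$rho_Q_2, 1)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  cfg <- simulation_config(b = 1.7, gamma = 1, alpha = 0.6, n = 300,
                           mcs_total = 200, window = 50, realizations = 1,
                           seed = 11)
  a <- simulate_coupled(cfg)
  b <- simulate_coupled(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg$seed <- 12L
  expect_false(identical(as.data.frame(simulate_coupled(cfg)),
                         as.data.frame(a)))
})

test_that("fraction trajectories are valid distributions and layer 1 stays classical", {
  cfg <- simulation_config(b = 1.9, gamma = 1.2, alpha = 0.9, n = 250,
                           mcs_total = 300, window = 100, realizations = 1,
                           seed = 13)
  traj <- simulate_coupled(cfg)
  expect_true(all(traj$rho_C_1 >= 0 & traj$rho_C_1 <= 1))
  expect_equal(traj$rho_C_1 + traj$rho_D_1, rep(1, nrow(traj)))
  expect_equal(traj$rho_C_2 + traj$rho_D_2 + traj$rho_Q_2, rep(1, nrow(traj)))
  fin <- attr(traj, "final_state")
  expect_true(all(fin$strategies1 %in% c(0L, 1L)))
  expect_true(all(fin$strategies2 %in% c(0L, 1L, 2L)))
})

test_that("with alpha = 0 the layer-1 trajectory is bit-identical across gamma", {
  base <- simulation_config(b = 1.6, gamma = 0, alpha = 0, n = 400,
                            mcs_total = 300, window = 100, realizations = 1,
                            seed = 21)
  t0 <- simulate_coupled(base)
  for (g in c(0.4, pi / 2)) {
    alt <- base
    alt$gamma <- g
    tg <- simulate_coupled(alt)
    expect_identical(tg$rho_C_1, t0$rho_C_1)
    expect_identical(tg$rho_D_1, t0$rho_D_1)
    # ... while the QPD layer itself does respond to gamma
    expect_false(identical(tg$rho_Q_2, t0$rho_Q_2))
  }
})

test_that("frozen-payoff and shuffled-order modes run and stay valid", {
  for (mode in list(list(payoff_mode = "frozen"),
                    list(update_order = "shuffled"))) {
    cfg <- do.call(simulation_config,
                   c(list(b = 1.5, gamma = 0.8, alpha = 0.5, n = 200,
                          mcs_total = 100, window = 20, realizations = 1,
                          seed = 3), mode))
    traj <- simulate_coupled(cfg)
    expect_equal(nrow(traj), 101L)
    expect_equal(traj$rho_C_2 + traj$rho_D_2 + traj$rho_Q_2,
                 rep(1, nrow(traj)))
  }
})

test_that("trajectories export to the documented CSV layout", {
  cfg <- simulation_config(b = 1.2, n = 100, mcs_total = 5, window = 2,
                           realizations = 1, seed = 2)
  traj <- simulate_coupled(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("mcs", "rho_C_1", "rho_D_1", "rho_C_2",
                                  "rho_D_2", "rho_Q_2"))
  expect_equal(back$rho_Q_2, traj$rho_Q_2)
})
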