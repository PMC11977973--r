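test_that("bursty burst family matches the geometric closed forms", {
  alpha <- 0.0282; b <- 3.46
  net <- bursty_model(alpha, b, 120)
  a <- propensities(net, c(M = 0))
  # truncated total burst propensity = alpha * (1 - 1/(1+b)) up to tail mass
  expect_equal(sum(a), alpha * (1 - 1 / (1 + b)), tolerance = 1e-6 / sum(a))
  # mean production per unit time = alpha * b
  expect_equal(sum(seq_along(a) * a), alpha * b, tolerance = 1e-4)
  # truncation point honors the tail-mass bound
  r <- b / (1 + b)
  expect_lt(r^net$n_reactions, 1e-6)
  expect_gte(r^(net$n_reactions - 1L), 1e-6)

  # b -> 0 degenerates gracefully: tiny, nonnegative rates
  small <- bursty_model(alpha, 1e-4, 120)
  expect_true(all(propensities(small, c(M = 0)) >= 0))
  expect_lt(sum(propensities(small, c(M = 0))), alpha * 1e-3)
})

test_that("refractory gene states are conserved and silent without k4", {
  net <- refractory_model()
  tr <- ssa(net, t_final = 400, times = seq(0, 400, by = 1),
            method = "delay_mnr", seed = 14)
  gsum <- rowSums(tr$states[, c("G0", "G1", "G2")])
  expect_true(all(gsum == 1))
  expect_true(all(tr$states[, "M"] >= 0))

  off <- refractory_model(k4 = 0)
  tr0 <- ssa(off, t_final = 200, times = seq(0, 200, by = 1),
             method = "delay_mnr", seed = 15)
  expect_true(all(tr0$states[, "M"] == 0))
})

test_that("refractory G2 occupancy matches the renewal-cycle value", {
  # mean sojourns 1/k1 + 1/k2 + 1/k3; G2 fraction = (1/k3)/total = 0.5455
  net <- refractory_model(0.15, 0.1, 0.05, k4 = 0, tau = 1)
  ens <- ssa(net, t_final = 1500, times = seq(0, 1500, by = 1),
             method = "delay_mnr", n_samples = 4, seed = 16)
  occ <- mean(ens$states[ens$times > 50, "G2", ])
  expect_lt(abs(occ - 0.5455), 0.06)
})

test_that("concentration-to-molecule conversion is the exact B-rescaling", {
  ctx <- conversion_context(1e-20)
  expect_equal(ctx$B, 6023)
  # one concentration unit corresponds to B molecules
  expect_equal(1 * ctx$B, 6023)

  conc <- delaysim:::ast_ode_rhs_concentration(0.2)
  mol1 <- convert_concentration_model(conc, 1)
  set.seed(2)
  for (i in 1:5) {
    y <- runif(4, 0, 3)
    expect_equal(mol1$rhs(0, y, NULL)[[1]], conc(0, y, NULL)[[1]])
  }

  # molecule trajectories divided by B reproduce concentration trajectories
  B <- 6023
  molB <- convert_concentration_model(conc, B)
  y0 <- c(0.5, 0.5, 0.5, 0.5)
  ts <- c(0, 5, 20, 60)
  sol_c <- deSolve::ode(y0, ts, conc, NULL, rtol = 1e-10, atol = 1e-10)
  sol_m <- deSolve::ode(y0 * B, ts, molB$rhs, NULL, rtol = 1e-10, atol = 1e-8)
  expect_equal(sol_m[, -1] / B, sol_c[, -1], tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(convert_concentration_model(conc, -2), "positive")
})

test_that("AST ensemble means track the molecule-based ODE solution", {
  # law-of-large-numbers check at a reduced scale: the exact B-rescaling is
  # verified algebraically above, so a moderate B suffices here
  B <- 600
  net <- ast_model(alpha_s = 0.05, B = B)
  t_end <- 5
  ens <- ssa(net, t_final = t_end, times = c(0, t_end), method = "direct",
             n_samples = 40, seed = 70)
  m <- colMeans(ensemble_snapshot(ens, t_end))
  rhs <- ast_ode_rhs(0.05, B = B)
  ode_end <- deSolve::ode(c(0, 0, 0, 0), c(0, t_end), rhs, NULL,
                          rtol = 1e-8, atol = 1e-6)[2, -1]
  expect_equal(unname(m), unname(ode_end), tolerance = 0.06)
})

test_that("RNA velocity phases relax to the linear-network means and decay", {
  mod <- rna_velocity_model(alpha = 20, beta = 1, gamma = 0.5, t_switch = 50)
  ens <- simulate_rna_velocity(mod, t_final = 100, times = seq(0, 100, by = 1),
                               n_samples = 150, seed = 44)
  m_sw <- colMeans(ensemble_snapshot(ens, 50))
  expect_lt(abs(m_sw[["U"]] / 20 - 1), 0.1)   # E[U] = alpha / beta
  expect_lt(abs(m_sw[["S"]] / 40 - 1), 0.1)   # E[S] = alpha / gamma
  m_end <- colMeans(ensemble_snapshot(ens, 100))
  expect_lt(m_end[["U"]], 1)
  expect_lt(m_end[["S"]], 1)

  # delayed variant: pending degradations straddle the switch and both
  # species still return to the origin
  mod_d <- rna_velocity_model(alpha = 20, beta = 1, gamma = 0.5,
                              t_switch = 25, tau = 2)
  ens_d <- simulate_rna_velocity(mod_d, t_final = 60, times = seq(0, 60, by = 1),
                                 n_samples = 60, seed = 45)
  expect_true(all(ens_d$states >= 0))
  m_end_d <- colMeans(ensemble_snapshot(ens_d, 60))
  expect_lt(m_end_d[["U"]], 1)
  expect_lt(m_end_d[["S"]], 1.5)
  # determinism of the two-phase driver
  ens_d2 <- simulate_rna_velocity(mod_d, t_final = 60, times = seq(0, 60, by = 1),
                                  n_samples = 60, seed = 45)
  expect_identical(ens_d$states, ens_d2$states)
})

test_that("toggle switch settles into one of two exclusive states", {
  net <- toggle_model()
  ens <- ssa(net, t_final = 40, times = c(0, 40), method = "direct",
             n_samples = 30, seed = 90)
  fin <- ensemble_snapshot(ens, 40)
  winner <- fin[, "A"] > fin[, "B"]
  expect_true(any(winner) && any(!winner))       # both basins reached
  # mutual exclusion holds for the bulk; at these copy numbers a noticeable
  # minority of walkers is mid-transition near the ridge at any instant
  expect_gt(mean(abs(fin[, "A"] - fin[, "B"]) > 10), 0.6)
  # committed walkers are strongly polarised
  expect_gt(mean(abs(fin[, "A"] - fin[, "B"])), 20)
})
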