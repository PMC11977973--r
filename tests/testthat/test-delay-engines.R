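delay_methods <- c("delay_rejection", "delay_direct", "delay_mnr")

test_that("zero-delay networks reduce to the Markovian law", {
  net0 <- zero_delay_birth_death_net(10, 1)
  ref <- endpoint_samples(birth_death_net(10, 1), c(X = 0), "direct",
                          t = 8, n = 400, seed = 900)
  for (m in delay_methods) {
    s <- endpoint_samples(net0, c(X = 0), m, t = 8, n = 400, seed = 950)
    expect_true(ks_pass(s, ref), label = m)
  }
})

test_that("deterministic lifetimes give the M/D/infinity Poisson law", {
  # birth rate 5, each molecule lives exactly tau = 2: stationary Poisson(10)
  net <- delayed_birth_net(5, 2)
  for (m in delay_methods) {
    v <- stationary_samples(net, c(X = 0), m, t_each = 500, burnin = 20,
                            by = 2, n_traj = 4, seed = 61)
    expect_lt(abs(mean(v) / 10 - 1), 0.05, label = m)
    expect_true(var(v) / mean(v) > 0.85 && var(v) / mean(v) < 1.15, label = m)
  }
})

test_that("the three delay engines agree in distribution", {
  net <- delayed_birth_net(5, 2)
  samp <- lapply(stats::setNames(delay_methods, delay_methods),
                 function(m) endpoint_samples(net, c(X = 0), m, t = 5,
                                              n = 400, seed = 77))
  expect_true(ks_pass(samp$delay_rejection, samp$delay_direct))
  expect_true(ks_pass(samp$delay_rejection, samp$delay_mnr))
  expect_true(ks_pass(samp$delay_direct, samp$delay_mnr))
})

test_that("consuming and completion-only delays update the state as specified", {
  # one molecule, one (effectively instantaneous) firing, delay tau = 3
  grid <- c(0, 1, 2, 4, 5)
  consuming <- reaction_network(c("X", "Y"), list(
    reaction(reactants = c(X = 1), products = c(Y = 1), rate = 1e8,
             delay = delay_spec("consuming", value = 3))))
  tr <- ssa(consuming, c(X = 1, Y = 0), t_final = 5, times = grid,
            method = "delay_mnr", seed = 3)
  # X drops at firing (t ~ 0), Y appears only at completion (t ~ 3)
  expect_equal(unname(tr$states[, "X"]), c(1, 0, 0, 0, 0))
  expect_equal(unname(tr$states[, "Y"]), c(0, 0, 0, 1, 1))

  # completion-only: the reactant is untouched at initiation (and therefore
  # stays visible to the propensity until the delay elapses), and the whole
  # net change lands at t + tau. Checked on one hand-driven firing.
  completion <- reaction_network(c("X", "Y"), list(
    reaction(reactants = c(X = 1), products = c(Y = 1), rate = 1,
             delay = delay_spec("completion_only", value = 3))))
  expect_true(all(completion$S_matrix == 0))
  expect_equal(completion$S_delay_matrix[, 1], c(X = -1, Y = 1))
  plan <- delaysim:::compile_network(completion)
  q <- event_queue(2)
  x <- delaysim:::fire_delayed(plan, q, c(1, 0), t = 0.4, j = 1L)
  expect_equal(x, c(1, 0))                  # unchanged at initiation
  expect_equal(queue_size(q), 1L)
  expect_equal(q$committed, c(1, 0))        # the removal is committed, though
  ev <- pop_completion(q)
  expect_equal(ev$time, 3.4)
  expect_equal(x + ev$delta, c(0, 1))       # both updates land together
})

test_that("delay engines are deterministic given the seed", {
  net <- delayed_birth_net(5, 2)
  for (m in delay_methods) {
    a <- ssa(net, c(X = 0), t_final = 30, method = m, seed = 8)
    b <- ssa(net, c(X = 0), t_final = 30, method = m, seed = 8)
    expect_identical(a$states, b$states, label = m)
  }
})

test_that("counts never go negative when fast degradation races delayed removal", {
  # completion-only removal of X scheduled at rate 3 while a fast
  # non-delayed degradation consumes the same species: conflict-heavy
  net <- reaction_network("X", list(
    reaction(products = c(X = 1), rate = 20, name = "birth"),
    reaction(reactants = c(X = 1), rate = 3,
             delay = delay_spec("completion_only", value = 1),
             name = "slow_delayed_removal"),
    reaction(reactants = c(X = 1), rate = 4, name = "fast_removal")))
  for (m in delay_methods) {
    tr <- ssa(net, c(X = 0), t_final = 60, times = seq(0, 60, by = 0.25),
              method = m, seed = 13)
    expect_true(all(tr$states >= 0), label = m)
    expect_gt(mean(tr$states[tr$times > 10, 1]), 0)
  }
})

test_that("sampled delays draw a fresh lag at every firing", {
  set.seed(1)
  net <- reaction_network("X", list(
    reaction(rate = 5, delay = delay_spec("consuming",
                                          sampler = function() runif(1, 1, 3)),
             s_change = c(X = 1), s_delay_change = c(X = -1))))
  # lifetimes uniform on [1,3] (mean 2): stationary mean still 5 * 2 = 10
  v <- stationary_samples(net, c(X = 0), "delay_rejection", t_each = 600,
                          burnin = 20, by = 2, n_traj = 2, seed = 31)
  expect_lt(abs(mean(v) / 10 - 1), 0.08)
  # but the law is not Poisson-with-deterministic-lifetime: still Poisson
  # (M/G/infinity), so the Fano factor remains ~ 1
  expect_true(var(v) / mean(v) > 0.85 && var(v) / mean(v) < 1.15)
})

test_that("pending completions survive a phase hand-over", {
  net <- delayed_birth_net(5, 2)
  tr <- ssa(net, c(X = 0), t_final = 3, times = c(0, 3), method = "delay_mnr",
            seed = 4, keep_pending = TRUE)
  q <- tr$pending
  expect_s3_class(q, "pending_event_queue")
  expect_gt(queue_size(q), 0L)   # molecules born after t = 1 still pending
  # restart a dead network carrying the queue: every pending removal executes
  dead <- reaction_network("X", list(reaction(products = c(X = 1), rate = 0)))
  x_end <- unname(tr$states[2, 1])
  shifted <- q
  shifted$times[shifted$head:shifted$tail] <-
    shifted$times[shifted$head:shifted$tail] - 3
  tr2 <- ssa(dead, c(X = x_end), t_final = 5, times = c(0, 2.5, 5),
             method = "delay_mnr", seed = 5, pending = shifted)
  expect_equal(unname(tr2$states[3, 1]), 0)   # all lifetimes < 2 remain
})
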