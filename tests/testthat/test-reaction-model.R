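test_that("network construction materialises the three matrices", {
  net <- reaction_network("X", list(reaction(products = c(X = 1), rate = 1)))
  expect_equal(unname(net$S_matrix), matrix(1))
  expect_equal(unname(net$S_delay_matrix), matrix(0))
  expect_equal(unname(net$reactant_matrix), matrix(0))

  # non-delayed column is product - reactant stoichiometry
  net2 <- reaction_network(c("A", "B", "C"), list(
    reaction(reactants = c(A = 2, B = 1), products = c(C = 1, B = 1), rate = 0.3)))
  expect_equal(net2$S_matrix[, 1], c(A = -2, B = 0, C = 1))
  expect_equal(net2$reactant_matrix[, 1], c(A = 2, B = 1, C = 0))

  # the Bursty network defers all removals: S_delay strictly negative
  bn <- bursty_model(0.0282, 3.46, 120)
  expect_equal(bn$n_species, 1L)
  expect_true(all(bn$S_delay_matrix < 0))
  expect_equal(unname(bn$S_matrix[1, ]), -unname(bn$S_delay_matrix[1, ]))
})

test_that("construction rejects invalid networks", {
  expect_error(reaction_network(c("X", "X"),
                                list(reaction(products = c(X = 1), rate = 1))),
               "duplicate")
  expect_error(reaction_network("X", list(reaction(products = c(Y = 1), rate = 1))),
               "undeclared species")
  expect_error(reaction(products = c(X = 1), rate = -1), "nonnegative")
  # completion_only must defer all change
  expect_error(reaction_network("X", list(
    reaction(reactants = c(X = 1), rate = 1,
             delay = delay_spec("completion_only", value = 1),
             s_change = c(X = -1)))),
    "defer")
  # non-delayed reaction cannot carry a delayed change
  expect_error(reaction_network("X", list(
    reaction(products = c(X = 1), rate = 1, s_delay_change = c(X = 1)))),
    "delayed change")
})

test_that("mass-action propensity follows the combinatorial convention", {
  expect_equal(mass_action_propensity(2, c(0), c(99)), 2)     # zeroth order
  expect_equal(mass_action_propensity(1, c(1), c(5)), 5)      # first order
  expect_equal(mass_action_propensity(1, c(2), c(4)), 6)      # 4*3/2
  expect_equal(mass_action_propensity(0.5, c(3), c(5)), 5)    # 0.5 * 5*4*3/6
  expect_equal(mass_action_propensity(2, c(1, 1), c(3, 4)), 24)

  # below-stoichiometry states have propensity exactly zero
  expect_equal(mass_action_propensity(1, c(2), c(1)), 0)
  expect_equal(mass_action_propensity(1, c(3), c(2)), 0)

  # monotone nondecreasing in each reactant count
  for (nu in list(c(1), c(2), c(3))) {
    vals <- vapply(0:10, function(n) mass_action_propensity(1, nu, n), numeric(1))
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0))
  }
})

test_that("propensity vectors dispatch mass-action and custom rules", {
  net <- birth_death_net()
  expect_equal(propensities(net, c(X = 3)), c(10, 3))
  expect_equal(propensities(net, c(X = 0)), c(10, 0))

  # absorbing state of a purely first-order network
  net2 <- reaction_network(c("A", "B"), list(
    reaction(reactants = c(A = 1), products = c(B = 1), rate = 2),
    reaction(reactants = c(B = 1), rate = 3)))
  expect_equal(propensities(net2, c(A = 0, B = 0)), c(0, 0))

  # AST FOXA2 production at the origin is B * alpha_f
  astn <- ast_model(alpha_s = 0.05, B = 6023)
  a <- propensities(astn, c(F = 0, N = 0, P = 0, S = 0))
  expect_equal(a[[1]], 6023^3 * 2.9 / 6023^2, tolerance = 1e-12)
  expect_equal(a[[1]], 17466.7, tolerance = 1e-6)
  # degradations vanish at the origin
  expect_equal(a[c(2, 4, 6, 8)], rep(0, 4))

  # custom propensities must be nonnegative and finite
  bad <- reaction_network("X", list(
    reaction(products = c(X = 1), propensity = function(x) -1, name = "bad_prod")))
  expect_error(propensities(bad, c(X = 0)), "bad_prod")
})

test_that("apply_change reports deficits instead of clamping", {
  expect_equal(apply_change(c(3), c(-1)), list(counts = 2, deficit = integer(0)))
  r <- apply_change(c(0), c(-1))
  expect_equal(r$counts, -1)
  expect_equal(r$deficit, 1L)
  expect_equal(apply_change(c(2, 5), c(1, -2))$counts, c(3, 3))
  expect_error(apply_change(c(1), c(1, 1)), "length")
})

test_that("propensities stay finite and nonnegative along simulated paths", {
  net <- reaction_network(c("A", "B"), list(
    reaction(products = c(A = 1), rate = 4),
    reaction(reactants = c(A = 2), products = c(B = 1), rate = 0.3),
    reaction(reactants = c(B = 1), rate = 1)))
  tr <- ssa(net, c(A = 0, B = 0), t_final = 30, times = seq(0, 30, by = 0.5),
            method = "direct", seed = 42)
  for (i in seq_along(tr$times)) {
    a <- propensities(net, tr$states[i, ])
    expect_true(all(is.finite(a)) && all(a >= 0))
  }
})
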