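# Small networks used across the suite, built fresh in code.

birth_death_net <- function(birth = 10, death = 1) {
  reaction_network("X", list(
    reaction(products = c(X = 1), rate = birth, name = "birth"),
    reaction(reactants = c(X = 1), rate = death, name = "death")))
}

# birth with each molecule removed exactly tau after creation: the
# M/D/infinity queue, stationary count ~ Poisson(alpha * tau)
delayed_birth_net <- function(alpha = 5, tau = 2) {
  reaction_network("X", list(
    reaction(rate = alpha, delay = delay_spec("consuming", value = tau),
             s_change = c(X = 1), s_delay_change = c(X = -1),
             name = "birth_with_lifetime")))
}

# birth-death written with zero delays: same law as birth_death_net, but
# exercising the delay machinery
zero_delay_birth_death_net <- function(birth = 10, death = 1) {
  reaction_network("X", list(
    reaction(rate = birth, delay = delay_spec("consuming", value = 0),
             s_delay_change = c(X = 1), name = "birth"),
    reaction(reactants = c(X = 1), rate = death,
             delay = delay_spec("completion_only", value = 0), name = "death")))
}

frozen_net <- function(n0 = 7) {
  net <- reaction_network("X", list(reaction(products = c(X = 1), rate = 0)))
  attr(net, "default_initial") <- c(X = n0)
  net
}

# pooled stationary samples from a few long trajectories
stationary_samples <- function(net, initial, method, t_each, burnin, by,
                               n_traj, seed, species = 1L) {
  ens <- ssa(net, initial, t_final = t_each, times = seq(0, t_each, by = by),
             method = method, n_samples = n_traj, seed = seed)
  if (n_traj == 1L) return(ens$states[ens$times > burnin, species])
  as.vector(ens$states[ens$times > burnin, species, ])
}

# final states of many short trajectories (distribution at fixed t)
endpoint_samples <- function(net, initial, method, t, n, seed) {
  ens <- ssa(net, initial, t_final = t, times = c(0, t), method = method,
             n_samples = n, seed = seed)
  as.vector(ens$states[2L, 1L, ])
}
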