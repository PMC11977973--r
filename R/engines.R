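# Exact non-delay SSA engines: direct, first-reaction and modified next
# reaction. All three sample the same continuous-time Markov jump process and
# are distributionally equivalent; they differ only in how the next event is
# drawn. Output is the state sampled onto `out_times` (piecewise-constant:
# the state at an output time t is the state after all events with event
# time <= t). When every propensity is zero the state freezes to t_final.

# linear-scan categorical draw proportional to a; u is uniform on [0, sum(a))
pick_reaction <- function(a, u) {
  acc <- a[1L]
  j <- 1L
  while (acc < u) {
    j <- j + 1L
    acc <- acc + a[j]
  }
  j
}

engine_direct <- function(plan, x, t_final, out_times) {
  n_out <- length(out_times)
  states <- matrix(0, n_out, plan$ns)
  p <- 1L
  t <- 0
  prop <- plan$prop_fn
  Scols <- plan$S_cols
  EB <- rexp(1024L); eb <- 0L          # buffered RNG: per-call overhead
  UB <- runif(1024L); ub <- 0L         # dominates at this loop granularity
  repeat {
    a <- prop(x)
    a0 <- sum(a)
    if (!is.finite(a0)) stop("non-finite total propensity")
    if (a0 <= 0) break
    eb <- eb + 1L; if (eb > 1024L) { EB <- rexp(1024L); eb <- 1L }
    t_next <- t + EB[eb] / a0
    if (t_next > t_final) break
    while (p <= n_out && out_times[p] < t_next) { states[p, ] <- x; p <- p + 1L }
    ub <- ub + 1L; if (ub > 1024L) { UB <- runif(1024L); ub <- 1L }
    x <- x + Scols[[pick_reaction(a, UB[ub] * a0)]]
    t <- t_next
  }
  while (p <= n_out) { states[p, ] <- x; p <- p + 1L }
  states
}

engine_first_reaction <- function(plan, x, t_final, out_times) {
  n_out <- length(out_times)
  states <- matrix(0, n_out, plan$ns)
  p <- 1L
  t <- 0
  nr <- plan$nr
  prop <- plan$prop_fn
  Scols <- plan$S_cols
  repeat {
    a <- prop(x)
    if (any(!is.finite(a))) stop("non-finite propensity")
    pos <- a > 0
    if (!any(pos)) break
    # candidate firing time for every reaction; earliest wins
    dt <- rep(Inf, nr)
    dt[pos] <- rexp(sum(pos)) / a[pos]
    j <- which.min(dt)
    t_next <- t + dt[j]
    if (t_next > t_final) break
    while (p <= n_out && out_times[p] < t_next) { states[p, ] <- x; p <- p + 1L }
    x <- x + Scols[[j]]
    t <- t_next
  }
  while (p <= n_out) { states[p, ] <- x; p <- p + 1L }
  states
}

engine_mnr <- function(plan, x, t_final, out_times) {
  # Anderson's modified next reaction method: each reaction k carries an
  # internal clock T_k (elapsed internal time) and a threshold P_k (internal
  # time of its next firing, a unit-rate Poisson process).
  n_out <- length(out_times)
  states <- matrix(0, n_out, plan$ns)
  p <- 1L
  t <- 0
  nr <- plan$nr
  prop <- plan$prop_fn
  Scols <- plan$S_cols
  Tk <- numeric(nr)
  Pk <- rexp(nr)
  EB <- rexp(1024L); eb <- 0L
  repeat {
    a <- prop(x)
    if (any(!is.finite(a))) stop("non-finite propensity")
    dt <- (Pk - Tk) / a
    dt[a <= 0] <- Inf
    j <- which.min(dt)
    dtj <- dt[j]
    if (!is.finite(dtj)) break
    t_next <- t + dtj
    if (t_next > t_final) break
    while (p <= n_out && out_times[p] < t_next) { states[p, ] <- x; p <- p + 1L }
    Tk <- Tk + a * dtj
    eb <- eb + 1L; if (eb > 1024L) { EB <- rexp(1024L); eb <- 1L }
    Pk[j] <- Pk[j] + EB[eb]
    x <- x + Scols[[j]]
    t <- t_next
  }
  while (p <= n_out) { states[p, ] <- x; p <- p + 1L }
  states
}
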