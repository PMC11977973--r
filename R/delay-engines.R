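# Exact delay-capable engines. All three maintain the pending-completion
# queue; they differ in how the next reaction firing is sampled:
#   delay_rejection -- tentative Exp(a0) step, rejected (and redrawn, which
#     is exact by memorylessness) whenever a scheduled completion intervenes;
#   delay_direct -- the waiting time is solved exactly by integrating the
#     piecewise-constant total propensity across completion times, with
#     propensities re-evaluated after each completion is applied;
#   delay_mnr -- Anderson's modified next reaction method with per-reaction
#     internal clocks; the next event is the earlier of the earliest internal
#     firing and the earliest completion.
# A completion tied with a sampled firing at the identical instant executes
# first: completions were committed in the past, and the deterministic order
# keeps runs reproducible.

# Apply the firing of reaction j at time t. Mutates the queue; returns the
# new state. Any committed-decrement deficit (including a negative count
# proposed by a custom propensity) goes through resolve_conflict, which
# errors when no pending event can be removed to repair it.
fire_delayed <- function(plan, q, x, t, j) {
  kind <- plan$delay_kind[j]
  x <- x + plan$S_cols[[j]]
  if (kind != 0L) {
    tau <- draw_delay(plan, j)
    delta <- plan$comp_cols[[j]]
    if (tau == 0) {
      x <- x + delta
    } else {
      schedule_completion(q, t + tau, delta, j)
    }
  }
  if (any(x < q$committed) || any(x < 0)) {
    if (any(x < 0) && queue_size(q) == 0L)
      stop(sprintf("firing %s drove a count negative", plan$rnames[j]))
    resolve_conflict(q, x)
    if (any(x < 0))
      stop(sprintf("firing %s drove a count negative", plan$rnames[j]))
  }
  x
}

engine_delay_rejection <- function(plan, x, t_final, out_times, q) {
  n_out <- length(out_times)
  states <- matrix(0, n_out, plan$ns)
  p <- 1L
  t <- 0
  prop <- plan$prop_fn
  EB <- rexp(1024L); eb <- 0L
  UB <- runif(1024L); ub <- 0L
  repeat {
    a <- prop(x)
    a0 <- sum(a)
    if (!is.finite(a0)) stop("non-finite total propensity")
    tc <- queue_peek(q)
    if (a0 <= 0) {
      if (tc > t_final) break
      while (p <= n_out && out_times[p] < tc) { states[p, ] <- x; p <- p + 1L }
      ev <- pop_completion(q)
      x <- x + ev$delta
      t <- tc
      next
    }
    eb <- eb + 1L; if (eb > 1024L) { EB <- rexp(1024L); eb <- 1L }
    t_next <- t + EB[eb] / a0
    if (t_next >= tc) {               # completion intervenes: reject the step
      if (tc > t_final) break
      while (p <= n_out && out_times[p] < tc) { states[p, ] <- x; p <- p + 1L }
      ev <- pop_completion(q)
      x <- x + ev$delta
      t <- tc
    } else {
      if (t_next > t_final) break
      while (p <= n_out && out_times[p] < t_next) { states[p, ] <- x; p <- p + 1L }
      ub <- ub + 1L; if (ub > 1024L) { UB <- runif(1024L); ub <- 1L }
      x <- fire_delayed(plan, q, x, t_next, pick_reaction(a, UB[ub] * a0))
      t <- t_next
    }
  }
  while (p <= n_out) { states[p, ] <- x; p <- p + 1L }
  states
}

engine_delay_direct <- function(plan, x, t_final, out_times, q) {
  n_out <- length(out_times)
  states <- matrix(0, n_out, plan$ns)
  p <- 1L
  t <- 0
  prop <- plan$prop_fn
  a <- prop(x)
  a0 <- sum(a)
  EB <- rexp(1024L); eb <- 0L
  UB <- runif(1024L); ub <- 0L
  repeat {
    if (!is.finite(a0)) stop("non-finite total propensity")
    eb <- eb + 1L; if (eb > 1024L) { EB <- rexp(1024L); eb <- 1L }
    target <- EB[eb]                  # unit-exponential internal target
    fired <- FALSE
    repeat {
      tc <- queue_peek(q)
      t_fire <- if (a0 > 0) t + target / a0 else Inf
      if (t_fire < tc) {
        if (t_fire > t_final) break
        while (p <= n_out && out_times[p] < t_fire) { states[p, ] <- x; p <- p + 1L }
        ub <- ub + 1L; if (ub > 1024L) { UB <- runif(1024L); ub <- 1L }
        x <- fire_delayed(plan, q, x, t_fire, pick_reaction(a, UB[ub] * a0))
        t <- t_fire
        fired <- TRUE
        break
      }
      if (tc > t_final) break
      target <- target - a0 * (tc - t)   # consume the segment's hazard
      while (p <= n_out && out_times[p] < tc) { states[p, ] <- x; p <- p + 1L }
      ev <- pop_completion(q)
      x <- x + ev$delta
      t <- tc
      a <- prop(x)
      a0 <- sum(a)
    }
    if (!fired) break
    a <- prop(x)
    a0 <- sum(a)
  }
  while (p <= n_out) { states[p, ] <- x; p <- p + 1L }
  states
}

engine_delay_mnr <- function(plan, x, t_final, out_times, q) {
  n_out <- length(out_times)
  states <- matrix(0, n_out, plan$ns)
  p <- 1L
  t <- 0
  nr <- plan$nr
  prop <- plan$prop_fn
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
    t_next <- t + dtj
    tc <- queue_peek(q)
    if (tc <= t_next) {               # completion first (incl. exact ties)
      if (tc > t_final) break
      while (p <= n_out && out_times[p] < tc) { states[p, ] <- x; p <- p + 1L }
      Tk <- Tk + a * (tc - t)
      ev <- pop_completion(q)
      x <- x + ev$delta
      t <- tc
    } else {
      if (!is.finite(dtj) || t_next > t_final) break
      while (p <= n_out && out_times[p] < t_next) { states[p, ] <- x; p <- p + 1L }
      Tk <- Tk + a * dtj
      eb <- eb + 1L; if (eb > 1024L) { EB <- rexp(1024L); eb <- 1L }
      Pk[j] <- Pk[j] + EB[eb]
      x <- fire_delayed(plan, q, x, t_next, j)
      t <- t_next
    }
  }
  while (p <= n_out) { states[p, ] <- x; p <- p + 1L }
  states
}
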