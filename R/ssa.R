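#' Available simulation engines
#'
#' Three exact non-delay algorithms (`"direct"`, `"first_reaction"`,
#' `"mnr"`) and three exact delay-capable algorithms (`"delay_rejection"`,
#' `"delay_direct"`, `"delay_mnr"`). All six sample the same process law on
#' networks they support; the delay engines additionally execute the
#' pending-completion queue.
#'
#' @return character vector of engine names.
#' @export
ssa_methods <- function() {
  c("direct", "first_reaction", "mnr",
    "delay_rejection", "delay_direct", "delay_mnr")
}

delay_capable <- function(method) {
  method %in% c("delay_rejection", "delay_direct", "delay_mnr")
}

upgrade_method <- function(method) {
  switch(method,
         direct = "delay_direct",
         first_reaction = "delay_rejection",
         mnr = "delay_mnr",
         method)
}

#' Simulate a reaction network exactly
#'
#' Runs one of six exact stochastic simulation algorithms on a
#' [reaction_network()], sampling the piecewise-constant state path onto an
#' output time grid (the state reported at grid time `t` is the state after
#' all events with event time `<= t`). With `n_samples > 1` an ensemble of
#' independent trajectories is produced; replicate `i` is seeded with
#' `seed + i - 1`, so ensembles are reproducible and individual replicates
#' can be re-run in isolation.
#'
#' A network with delayed reactions requires a delay-capable engine; if a
#' non-delay engine is requested for such a network it is upgraded to its
#' delay counterpart with a warning. When every propensity vanishes and no
#' completions are pending, the state freezes to the horizon (absorbing
#' states are legitimate model behaviour, not an error).
#'
#' @param network a [reaction_network()].
#' @param initial named (or species-ordered) vector of initial counts;
#'   defaults to the network's `default_initial` attribute when the model
#'   constructor provides one.
#' @param t_final simulation horizon (> 0).
#' @param times output grid, sorted within `[0, t_final]`; default a uniform
#'   grid of `n_points` values from 0 to `t_final`.
#' @param n_points grid size used when `times` is NULL (default 101).
#' @param method one of [ssa_methods()], or `"auto"` (direct /
#'   delay_rejection depending on the network).
#' @param n_samples number of independent trajectories.
#' @param seed integer seed; drawn (and recorded in the result) when NULL.
#' @param pending initial pending-event queue (advanced simulation restart,
#'   e.g. continuing a phase with scheduled completions still alive); a
#'   [event_queue()] whose times are relative to 0.
#' @param keep_pending if TRUE, attach the final queue of each trajectory.
#' @return `ssa_trajectory` when `n_samples == 1`, else `ssa_ensemble`.
#' @examples
#' net <- reaction_network("X", list(
#'   reaction(products = c(X = 1), rate = 10),
#'   reaction(reactants = c(X = 1), rate = 1)))
#' tr <- ssa(net, c(X = 0), t_final = 20, seed = 1)
#' head(tr$states)
#' @export
ssa <- function(network, initial = NULL, t_final, times = NULL, n_points = 101L,
                method = "auto", n_samples = 1L, seed = NULL,
                pending = NULL, keep_pending = FALSE) {
  stopifnot(inherits(network, "reaction_network"))
  if (!is.numeric(t_final) || length(t_final) != 1L || t_final <= 0)
    stop("`t_final` must be a single positive number")
  if (is.null(initial)) {
    initial <- attr(network, "default_initial")
    if (is.null(initial))
      stop("`initial` is required (this network has no default initial state)")
  }
  x0 <- resolve_counts(initial, network$species)
  if (any(x0 != round(x0))) stop("initial counts must be integers")
  if (is.null(times)) times <- seq(0, t_final, length.out = n_points)
  if (is.unsorted(times) || any(times < 0) || any(times > t_final))
    stop("`times` must be sorted within [0, t_final]")
  if (identical(method, "auto"))
    method <- if (network$has_delay || !is.null(pending)) "delay_rejection" else "direct"
  method <- match.arg(method, ssa_methods())
  if ((network$has_delay || !is.null(pending)) && !delay_capable(method)) {
    up <- upgrade_method(method)
    warning(sprintf("network has delayed reactions; using %s instead of %s", up, method))
    method <- up
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seed <- as.integer(seed)
  plan <- compile_network(network)
  engine <- switch(method,
                   direct = engine_direct,
                   first_reaction = engine_first_reaction,
                   mnr = engine_mnr,
                   delay_rejection = engine_delay_rejection,
                   delay_direct = engine_delay_direct,
                   delay_mnr = engine_delay_mnr)
  n_samples <- as.integer(n_samples)
  one <- function(i) {
    set.seed(seed + i - 1L)
    if (delay_capable(method)) {
      q <- clone_queue(pending, network$n_species)
      st <- engine(plan, x0, t_final, times, q)
      if (keep_pending) attr(st, "pending") <- q
      st
    } else {
      engine(plan, x0, t_final, times)
    }
  }
  if (n_samples == 1L) {
    st <- one(1L)
    out <- structure(list(times = times,
                          states = `colnames<-`(unclass(st), network$species),
                          species = network$species,
                          method = method, seed = seed),
                     class = "ssa_trajectory")
    if (keep_pending) out$pending <- attr(st, "pending")
    out
  } else {
    arr <- array(0, dim = c(length(times), network$n_species, n_samples),
                 dimnames = list(NULL, network$species, NULL))
    pend <- if (keep_pending) vector("list", n_samples) else NULL
    for (i in seq_len(n_samples)) {
      st <- one(i)
      arr[, , i] <- st
      if (keep_pending) pend[[i]] <- attr(st, "pending")
    }
    structure(list(times = times, states = arr, species = network$species,
                   method = method, seed = seed, n_samples = n_samples,
                   pending = pend),
              class = "ssa_ensemble")
  }
}

# deep-copy a queue so replicates do not share the mutable environment
clone_queue <- function(pending, ns) {
  q <- event_queue(ns)
  if (is.null(pending)) return(q)
  stopifnot(inherits(pending, "pending_event_queue"))
  if (pending$ns != ns) stop("pending queue species count mismatch")
  if (queue_size(pending) > 0L) {
    for (k in pending$head:pending$tail)
      if (!pending$dead[k])
        schedule_completion(q, pending$times[k], pending$delta[, k], pending$rxn[k])
  }
  q
}

#' Simulate method for reaction networks
#'
#' [stats::simulate()] interface: `simulate(net, nsim, seed, ...)` is
#' equivalent to `ssa(net, ..., n_samples = nsim, seed = seed)`.
#'
#' @param object a [reaction_network()].
#' @param nsim number of trajectories.
#' @param seed integer seed.
#' @param ... passed to [ssa()] (`initial`, `t_final`, `times`, `method`...).
#' @return see [ssa()].
#' @export
simulate.reaction_network <- function(object, nsim = 1, seed = NULL, ...) {
  ssa(object, n_samples = nsim, seed = seed, ...)
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory (%s): %d species, %d output times in [%g, %g]\n",
              x$method, length(x$species), length(x$times),
              min(x$times), max(x$times)))
  cat("final state:", paste(sprintf("%s = %g", x$species,
                                    x$states[nrow(x$states), ]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat(sprintf("SSA ensemble (%s): %d trajectories, %d species, %d output times\n",
              x$method, x$n_samples, length(x$species), length(x$times)))
  fin <- x$states[length(x$times), , , drop = FALSE]
  m <- apply(fin, 2, mean)
  cat("mean final state:", paste(sprintf("%s = %.3g", x$species, m), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ssa_ensemble <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$times[length(object$times)]
  out <- do.call(rbind, lapply(times, function(t) {
    snap <- ensemble_snapshot(object, t)
    data.frame(time = t, species = object$species,
               mean = colMeans(snap),
               var = apply(snap, 2, stats::var),
               row.names = NULL)
  }))
  class(out) <- c("summary.ssa_ensemble", "data.frame")
  out
}

#' @export
plot.ssa_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "s", lty = 1,
                    xlab = "time", ylab = "molecule count", ...)
  graphics::legend("topright", legend = x$species, lty = 1,
                   col = seq_along(x$species), bty = "n")
  invisible(x)
}

#' @export
plot.ssa_ensemble <- function(x, ...) {
  m <- apply(x$states, c(1, 2), mean)
  graphics::matplot(x$times, m, type = "l", lty = 1,
                    xlab = "time", ylab = "mean molecule count", ...)
  graphics::legend("topright", legend = x$species, lty = 1,
                   col = seq_along(x$species), bty = "n")
  invisible(x)
}

#' Ensemble states at a fixed time
#'
#' Piecewise-constant lookup of every trajectory's state at time `t` (the
#' nearest output grid point at or before `t`).
#'
#' @param ensemble an `ssa_ensemble` (or a single `ssa_trajectory`, giving a
#'   one-row matrix).
#' @param t a time within the simulated horizon.
#' @return matrix with one row per trajectory and one column per species.
#' @export
ensemble_snapshot <- function(ensemble, t) {
  if (inherits(ensemble, "ssa_trajectory")) {
    i <- snapshot_index(ensemble$times, t)
    m <- ensemble$states[i, , drop = FALSE]
    rownames(m) <- NULL
    return(m)
  }
  stopifnot(inherits(ensemble, "ssa_ensemble"))
  i <- snapshot_index(ensemble$times, t)
  m <- t(ensemble$states[i, , , drop = TRUE])
  if (length(ensemble$species) == 1L) m <- matrix(m, ncol = 1L)
  colnames(m) <- ensemble$species
  m
}

snapshot_index <- function(times, t) {
  if (t < times[1] || t > times[length(times)])
    stop("snapshot time outside the simulated output grid")
  findInterval(t, times)
}

#' Pool ensemble states across several snapshot times
#'
#' Stacks [ensemble_snapshot()] matrices at each requested time; useful for
#' stationary statistics and landscape estimation, where late-time snapshots
#' across trajectories are interchangeable draws.
#'
#' @param ensemble an `ssa_ensemble`.
#' @param times snapshot times within the output grid.
#' @return matrix with `n_samples * length(times)` rows.
#' @export
pool_snapshots <- function(ensemble, times) {
  do.call(rbind, lapply(times, function(t) ensemble_snapshot(ensemble, t)))
}
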