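#' Delay specification for a reaction
#'
#' Describes whether and how a reaction is delayed. Two delay classes are
#' supported, mirroring the standard taxonomy of delayed reactions:
#'
#' * `"consuming"` -- the state is adjusted twice: the immediate change
#'   (typically removal of reactants) is applied when the reaction fires at
#'   time `t`, and the delayed change (typically addition of products) is
#'   applied when the delay completes at `t + tau`.
#' * `"completion_only"` -- nothing changes when the reaction initiates; the
#'   entire net change is applied at `t + tau`.
#'
#' The delay `tau` is either a fixed nonnegative constant (in model time
#' units) or drawn afresh at every firing from `sampler`, a function of no
#' arguments that uses R's RNG and returns a nonnegative value.
#'
#' @param kind one of `"none"`, `"consuming"`, `"completion_only"`.
#' @param value nonnegative constant delay; mutually exclusive with `sampler`.
#' @param sampler function() returning one nonnegative delay draw.
#' @return an object of class `delay_spec`.
#' @examples
#' delay_spec("completion_only", value = 120)
#' delay_spec("consuming", sampler = function() rgamma(1, shape = 4, rate = 2))
#' @export
delay_spec <- function(kind = c("none", "consuming", "completion_only"),
                       value = NULL, sampler = NULL) {
  kind <- match.arg(kind)
  if (kind == "none") {
    if (!is.null(value) || !is.null(sampler))
      stop("delay kind 'none' must not carry a delay value or sampler")
  } else {
    if (is.null(value) == is.null(sampler))
      stop("a delayed reaction needs exactly one of `value` or `sampler`")
    if (!is.null(value)) {
      if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0)
        stop("constant delay must be a single finite nonnegative number")
      value <- as.numeric(value)
    }
    if (!is.null(sampler) && !is.function(sampler))
      stop("`sampler` must be a function")
  }
  structure(list(kind = kind, value = value, sampler = sampler),
            class = "delay_spec")
}

#' @export
print.delay_spec <- function(x, ...) {
  if (x$kind == "none") cat("<no delay>\n")
  else if (!is.null(x$value)) cat(sprintf("<%s delay, tau = %g>\n", x$kind, x$value))
  else cat(sprintf("<%s delay, sampled tau>\n", x$kind))
  invisible(x)
}

#' Define one reaction of a network
#'
#' A reaction is described by its reactant stoichiometry (which also sets the
#' propensity order under mass-action kinetics), its product stoichiometry,
#' and either a mass-action rate constant or an arbitrary custom propensity
#' function of the state. Delays are attached with [delay_spec()].
#'
#' For non-delayed reactions the net state change at firing is
#' `products - reactants`. For `"consuming"` delayed reactions the reactants
#' are removed at firing and the products appear at completion; for
#' `"completion_only"` reactions the whole change `products - reactants` is
#' deferred to completion. When a reaction does not fit the reactant/product
#' template (e.g. birth now, scheduled death of the same molecules later),
#' the immediate and delayed change vectors can be given explicitly via
#' `s_change` and `s_delay_change`, which override the derived columns of the
#' stoichiometric matrices.
#'
#' @param reactants named integer vector of consumed species counts (may be
#'   empty/NULL for zeroth-order reactions).
#' @param products named integer vector of produced species counts.
#' @param rate nonnegative mass-action rate constant (per model time unit).
#' @param propensity optional custom propensity: a function taking the named
#'   vector of current molecule counts and returning a nonnegative finite
#'   rate. When given, `rate` is ignored for propensity evaluation.
#' @param delay a [delay_spec()]; default no delay.
#' @param s_change optional named vector: explicit immediate state change.
#' @param s_delay_change optional named vector: explicit state change at
#'   delay completion.
#' @param name optional reaction label used in error messages.
#' @return an object of class `ssa_reaction`.
#' @examples
#' reaction(products = c(X = 1), rate = 10)                   # 0 -> X
#' reaction(reactants = c(X = 1), rate = 1)                   # X -> 0
#' reaction(reactants = c(X = 1), products = c(Y = 1),
#'          delay = delay_spec("consuming", value = 2))       # X -> (tau) -> Y
#' @export
reaction <- function(reactants = NULL, products = NULL, rate = NULL,
                     propensity = NULL, delay = delay_spec("none"),
                     s_change = NULL, s_delay_change = NULL, name = NULL) {
  chk_named <- function(v, what) {
    if (is.null(v) || length(v) == 0L) return(NULL)
    if (is.null(names(v)) || any(!nzchar(names(v))))
      stop(sprintf("`%s` must be a named vector", what))
    if (!is.numeric(v) || any(!is.finite(v)))
      stop(sprintf("`%s` must be finite numeric", what))
    v
  }
  reactants <- chk_named(reactants, "reactants")
  products  <- chk_named(products, "products")
  s_change  <- chk_named(s_change, "s_change")
  s_delay_change <- chk_named(s_delay_change, "s_delay_change")
  if (!is.null(reactants) && any(reactants < 0 | reactants != round(reactants)))
    stop("reactant counts must be nonnegative integers")
  if (!is.null(products) && any(products < 0 | products != round(products)))
    stop("product counts must be nonnegative integers")
  if (!inherits(delay, "delay_spec")) stop("`delay` must be a delay_spec()")
  if (is.null(propensity)) {
    if (is.null(rate)) stop("a reaction needs a `rate` or a `propensity`")
    if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
      stop("`rate` must be a single finite nonnegative number")
  } else if (!is.function(propensity)) {
    stop("`propensity` must be a function of the count vector")
  }
  structure(list(reactants = reactants, products = products,
                 rate = if (is.null(rate)) NA_real_ else as.numeric(rate),
                 propensity = propensity, delay = delay,
                 s_change = s_change, s_delay_change = s_delay_change,
                 name = name),
            class = "ssa_reaction")
}

#' @export
print.ssa_reaction <- function(x, ...) {
  side <- function(v) {
    if (is.null(v) || length(v) == 0L) return("0")
    paste(ifelse(v == 1, names(v), paste0(v, " ", names(v))), collapse = " + ")
  }
  lab <- if (is.null(x$name)) "" else paste0(x$name, ": ")
  kin <- if (is.function(x$propensity)) "custom propensity" else sprintf("c = %g", x$rate)
  del <- if (x$delay$kind == "none") "" else
    sprintf(" [%s delay]", x$delay$kind)
  cat(sprintf("%s%s -> %s  (%s)%s\n", lab, side(x$reactants), side(x$products), kin, del))
  invisible(x)
}

# expand a named vector onto the full species axis
resolve_species <- function(v, species, what, rname) {
  out <- numeric(length(species))
  if (is.null(v)) return(out)
  unknown <- setdiff(names(v), species)
  if (length(unknown))
    stop(sprintf("reaction %s: %s refers to undeclared species: %s",
                 rname, what, paste(unknown, collapse = ", ")))
  out[match(names(v), species)] <- as.numeric(v)
  out
}

#' Build a validated reaction network
#'
#' Assembles species and reactions into a network with the three matrices the
#' simulators run on: the reactant matrix (stoichiometric orders used by
#' mass-action propensities), the immediate stoichiometric change matrix `S`
#' (applied when a reaction fires) and the delayed change matrix `S_delay`
#' (applied when the reaction's delay completes). Each matrix has one row per
#' species and one column per reaction; reaction order is preserved.
#'
#' @param species character vector of unique, non-empty species names.
#' @param reactions list of [reaction()] objects.
#' @return an object of class `reaction_network`.
#' @examples
#' net <- reaction_network("X", list(
#'   reaction(products = c(X = 1), rate = 10),
#'   reaction(reactants = c(X = 1), rate = 1)))
#' net
#' @export
reaction_network <- function(species, reactions) {
  if (!is.character(species) || length(species) < 1L)
    stop("`species` must be a character vector with at least one name")
  if (anyDuplicated(species)) stop("duplicate species name")
  if (any(!nzchar(species))) stop("species names must be non-empty")
  if (inherits(reactions, "ssa_reaction")) reactions <- list(reactions)
  if (!is.list(reactions) || length(reactions) < 1L)
    stop("`reactions` must be a non-empty list of reaction() objects")
  ns <- length(species)
  nr <- length(reactions)
  nu <- matrix(0, ns, nr, dimnames = list(species, NULL))
  S  <- matrix(0, ns, nr, dimnames = list(species, NULL))
  Sd <- matrix(0, ns, nr, dimnames = list(species, NULL))
  for (j in seq_len(nr)) {
    r <- reactions[[j]]
    if (!inherits(r, "ssa_reaction"))
      stop(sprintf("reactions[[%d]] is not a reaction() object", j))
    rname <- if (is.null(r$name)) as.character(j) else sQuote(r$name)
    nu[, j] <- resolve_species(r$reactants, species, "reactants", rname)
    prod_j  <- resolve_species(r$products, species, "products", rname)
    kind <- r$delay$kind
    if (kind == "none") {
      S[, j] <- prod_j - nu[, j]
    } else if (kind == "consuming") {
      S[, j]  <- -nu[, j]
      Sd[, j] <- prod_j
    } else { # completion_only
      Sd[, j] <- prod_j - nu[, j]
    }
    if (!is.null(r$s_change))
      S[, j] <- resolve_species(r$s_change, species, "s_change", rname)
    if (!is.null(r$s_delay_change))
      Sd[, j] <- resolve_species(r$s_delay_change, species, "s_delay_change", rname)
    if (kind == "none" && any(Sd[, j] != 0))
      stop(sprintf("reaction %s: non-delayed reaction has a nonzero delayed change", rname))
    if (kind == "completion_only" && any(S[, j] != 0))
      stop(sprintf("reaction %s: completion_only reaction must defer all change", rname))
    if (!is.function(r$propensity) && (is.na(r$rate) || r$rate < 0))
      stop(sprintf("reaction %s: mass-action reaction needs a nonnegative rate", rname))
  }
  structure(list(species = species, reactions = reactions,
                 reactant_matrix = nu, S_matrix = S, S_delay_matrix = Sd,
                 n_species = ns, n_reactions = nr,
                 has_delay = any(vapply(reactions, function(r) r$delay$kind != "none", logical(1)))),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions%s\n",
              x$n_species, x$n_reactions,
              if (x$has_delay) " (with delays)" else ""))
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions) print(r)
  invisible(x)
}

#' @export
summary.reaction_network <- function(object, ...) {
  kinds <- vapply(object$reactions, function(r) r$delay$kind, character(1))
  cat(sprintf("Reaction network: %d species, %d reactions\n",
              object$n_species, object$n_reactions))
  cat(sprintf("  delayed reactions: %d consuming, %d completion-only\n",
              sum(kinds == "consuming"), sum(kinds == "completion_only")))
  cat(sprintf("  custom propensities: %d\n",
              sum(vapply(object$reactions, function(r) is.function(r$propensity), logical(1)))))
  invisible(object)
}

#' Mass-action propensity of one reaction
#'
#' Uses the combinatorial (exact chemical-master-equation) convention: the
#' propensity of a reaction with rate constant `c` and reactant orders
#' `nu_i` at state `n` is `c * prod_i choose(n_i, nu_i)`, i.e.
#' `n (n - 1) / 2` for a homodimerisation, not `n^2`. States with fewer
#' molecules than the reaction consumes have propensity exactly 0.
#'
#' @param rate nonnegative rate constant.
#' @param reactant_counts per-species reactant stoichiometry `nu`.
#' @param counts per-species molecule counts `n` (same length).
#' @return a single nonnegative number.
#' @examples
#' mass_action_propensity(1, c(2), c(4))  # 2X -> ..., n = 4: 4*3/2 = 6
#' @export
mass_action_propensity <- function(rate, reactant_counts, counts) {
  if (length(reactant_counts) != length(counts))
    stop("`reactant_counts` and `counts` must have the same length")
  a <- rate
  for (i in which(reactant_counts > 0)) {
    a <- a * prod(counts[i] - seq_len(reactant_counts[i]) + 1) /
      factorial(reactant_counts[i])
    if (a <= 0) return(0)
  }
  max(a, 0)
}

#' Evaluate all reaction propensities at a state
#'
#' Returns the length-`n_reactions` propensity vector at molecule counts
#' `counts`, using each reaction's custom propensity function where present
#' and combinatorial mass-action kinetics otherwise. A custom propensity that
#' returns a negative or non-finite value is an error naming the reaction.
#'
#' @param network a [reaction_network()].
#' @param counts named or unnamed vector of molecule counts in species order.
#' @return numeric vector of nonnegative propensities.
#' @examples
#' net <- reaction_network("X", list(
#'   reaction(products = c(X = 1), rate = 10),
#'   reaction(reactants = c(X = 1), rate = 1)))
#' propensities(net, c(X = 3))  # c(10, 3)
#' @export
propensities <- function(network, counts) {
  stopifnot(inherits(network, "reaction_network"))
  counts <- resolve_counts(counts, network$species)
  plan <- compile_network(network)
  eval_propensities(plan, counts)
}

#' Apply a stoichiometric change, flagging deficits
#'
#' Elementwise sum of `counts + delta`. Rather than raising on a negative
#' result, the indices of species driven negative are returned so the caller
#' (in particular the delay engines) can distinguish an illegal proposal from
#' a conflict to be resolved by removing pending delayed events.
#'
#' @param counts per-species integer counts.
#' @param delta per-species integer change.
#' @return list with `counts` (the sum) and `deficit` (integer indices of
#'   species with a negative result; empty when the update is clean).
#' @examples
#' apply_change(c(3), c(-1))      # counts 2, no deficit
#' apply_change(c(0), c(-1))      # deficit on species 1
#' @export
apply_change <- function(counts, delta) {
  if (length(counts) != length(delta))
    stop("`counts` and `delta` must have the same length")
  out <- counts + delta
  list(counts = out, deficit = which(out < 0))
}

resolve_counts <- function(counts, species) {
  ns <- length(species)
  if (!is.null(names(counts))) {
    unknown <- setdiff(names(counts), species)
    if (length(unknown))
      stop("unknown species in counts: ", paste(unknown, collapse = ", "))
    full <- numeric(ns)
    full[match(names(counts), species)] <- counts
    counts <- full
  }
  if (length(counts) != ns)
    stop(sprintf("counts must have length %d (one per species)", ns))
  if (any(counts < 0)) stop("molecule counts must be nonnegative")
  as.numeric(counts)
}

# --- internal: compiled evaluation plan -------------------------------------
#
# Mass-action factors are grouped into "rounds" so each round touches every
# reaction at most once and evaluates with vectorised indexing; round k holds
# the k-th reactant species of each reaction. Custom propensities are plain
# closures called per step.
compile_network <- function(net) {
  ns <- net$n_species; nr <- net$n_reactions
  base <- numeric(nr)
  custom_idx <- integer(0)
  custom_fns <- list()
  fac_r <- list(); fac_s <- list(); fac_o <- list() # per round
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    if (is.function(r$propensity)) {
      custom_idx <- c(custom_idx, j)
      custom_fns[[length(custom_fns) + 1L]] <- r$propensity
    } else {
      base[j] <- r$rate
      sp <- which(net$reactant_matrix[, j] > 0)
      for (k in seq_along(sp)) {
        if (length(fac_r) < k) { fac_r[[k]] <- integer(0); fac_s[[k]] <- integer(0); fac_o[[k]] <- integer(0) }
        fac_r[[k]] <- c(fac_r[[k]], j)
        fac_s[[k]] <- c(fac_s[[k]], sp[k])
        fac_o[[k]] <- c(fac_o[[k]], as.integer(net$reactant_matrix[sp[k], j]))
      }
    }
  }
  rounds <- lapply(seq_along(fac_r), function(k)
    list(r = fac_r[[k]], s = fac_s[[k]], o = fac_o[[k]],
         o1 = which(fac_o[[k]] == 1L), o2 = which(fac_o[[k]] == 2L),
         ohi = which(fac_o[[k]] > 2L)))
  delay_kind <- vapply(net$reactions, function(r)
    switch(r$delay$kind, none = 0L, consuming = 1L, completion_only = 2L), integer(1))
  delay_const <- vapply(net$reactions, function(r)
    if (r$delay$kind != "none" && !is.null(r$delay$value)) r$delay$value else NA_real_,
    numeric(1))
  delay_samplers <- lapply(net$reactions, function(r) r$delay$sampler)
  # delta applied at completion: consuming defers S_delay; completion_only
  # defers the whole net change (its S column is all-zero by construction,
  # so S + S_delay is just S_delay, kept explicit for clarity)
  comp_delta <- net$S_delay_matrix + ifelse(matrix(delay_kind == 2L, net$n_species, nr, byrow = TRUE),
                                            net$S_matrix, 0)
  plan <- list(ns = ns, nr = nr, species = net$species,
       S = net$S_matrix, Sd = net$S_delay_matrix, comp_delta = comp_delta,
       S_cols = lapply(seq_len(nr), function(j) unname(net$S_matrix[, j])),
       comp_cols = lapply(seq_len(nr), function(j) unname(comp_delta[, j])),
       base = base, rounds = rounds,
       custom_idx = custom_idx, custom_fns = custom_fns,
       delay_kind = delay_kind, delay_const = delay_const,
       delay_samplers = delay_samplers,
       has_delay = net$has_delay,
       rnames = vapply(seq_len(nr), function(j) {
         nm <- net$reactions[[j]]$name
         if (is.null(nm)) sprintf("reaction %d", j) else nm
       }, character(1)))
  plan$prop_fn <- make_prop_fn(plan)
  plan
}

# specialise the propensity evaluator once per run: the per-step cost
# dominates everything else in a pure-R simulator
make_prop_fn <- function(plan) {
  base <- plan$base
  rounds <- plan$rounds
  ci <- plan$custom_idx
  fns <- plan$custom_fns
  species <- plan$species
  rnames <- plan$rnames
  if (length(ci) == 0L && length(rounds) == 0L) {
    # all reactions zeroth-order: constant propensities
    return(compiler::cmpfun(function(x) base))
  }
  simple <- length(rounds) == 1L && length(rounds[[1]]$o2) == 0L &&
    length(rounds[[1]]$ohi) == 0L
  if (simple) {
    # every mass-action reaction is zeroth- or first-order: the common case
    r1 <- rounds[[1]]$r
    s1 <- rounds[[1]]$s
    mass <- function(x) {
      a <- base
      a[r1] <- a[r1] * x[s1]
      a
    }
  } else {
    mass <- function(x) {
      a <- base
      for (rd in rounds) {
        xi <- x[rd$s]
        f <- xi
        if (length(rd$o2)) f[rd$o2] <- xi[rd$o2] * (xi[rd$o2] - 1) * 0.5
        for (k in rd$ohi) {
          o <- rd$o[k]
          f[k] <- prod(xi[k] - seq_len(o) + 1) / factorial(o)
        }
        a[rd$r] <- a[rd$r] * f
      }
      a[a < 0] <- 0   # sub-stoichiometric states
      a
    }
  }
  mass <- compiler::cmpfun(mass)
  if (length(ci) == 0L) return(mass)
  compiler::cmpfun(function(x) {
    a <- mass(x)
    xn <- x
    names(xn) <- species
    for (k in seq_along(ci)) {
      v <- fns[[k]](xn)
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
        stop(sprintf("custom propensity of %s returned an invalid value", rnames[ci[k]]))
      a[ci[k]] <- v
    }
    a
  })
}

eval_propensities <- function(plan, x) plan$prop_fn(x)

# fresh delay draw for reaction j
draw_delay <- function(plan, j) {
  tau <- plan$delay_const[j]
  if (is.na(tau)) {
    tau <- plan$delay_samplers[[j]]()
    if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
      stop(sprintf("delay sampler of %s returned an invalid delay", plan$rnames[j]))
  }
  tau
}
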